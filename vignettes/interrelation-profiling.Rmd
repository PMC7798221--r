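---
title: "Feature interrelation profiling with pointwise mutual information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature interrelation profiling with pointwise mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fip)
```

## The model

A compound set $S$ is viewed as a corpus in which each molecule is a
"sentence" and each binary fingerprint bit a "word". Borrowing the
linguistic notion of pointwise mutual information (PMI), the strength of
the association between two structural features $x$ and $y$ is

$$PMI(x, y) = \log_2 \frac{p(x, y)}{p(x)\,p(y)},$$

where $p(x)$, $p(y)$ are the probabilities of observing each feature in a
compound of $S$ and $p(x,y)$ the probability of observing both in the same
compound. $PMI = 1$ means the pair co-occurs twice as often as independence
predicts; $PMI = -1$ half as often; $PMI = 0$ means independence — note
that two features present in *every* compound have $PMI = 0$ even though
they drive pairwise Tanimoto similarity up, which is why a compound set can
simultaneously look redundant by mean Tanimoto and diverse by its PMI
profile.

The estimates are organized in four relation matrices over the $D$ feature
bits:

* **CORM** — co-occurrence counts, $\sum_{o=1}^{|S|} k_o k_o^T$ over the
  feature vectors $k_o$ (diagonal: single-feature counts);
* **COPRM** — CORM divided by $|S|$: probabilities;
* **PMIRM** — PMI of every feature pair; the *interrelation profile* of $S$;
* **ZPMIRM** — PMIRM standardized to Z-scores, which removes the global
  shift that overlapping (e.g. nested circular) features impose on the PMI
  distribution.

How well a query set $S$ (possibly a single compound) fits a reference
profile $S'$ is the *relative feature tightness*

$$RFT = \mu\!\left(COPRM(S) \times PMIRM(S')\right), \qquad
  ZRFT = \mu\!\left(COPRM(S) \times ZPMIRM(S')\right),$$

with $\times$ element-wise and $\mu$ a mean over matrix cells. Positive
ZRFT: the query's feature pairs are rated above average in the reference
profile. RFT/ZRFT is deliberately not symmetric and is not a metric.

## Conventions and numerical choices

Several conventions are under-determined by the formulas above; the
package fixes them as follows and exposes the consequential ones as
arguments:

* **Hadamard product.** The $\times$ in RFT/ZRFT is element-wise. Matrix
  multiplication would neither match the interpretation (query pair
  probabilities weighting reference pair scores) nor produce a scale-free
  mean.
* **Undefined cells.** A PMIRM cell is undefined iff $p(x,y) = 0$ — this
  covers both never-observed features and feature pairs that individually
  occur but never co-occur. Undefined cells are masked (`NA`), never
  smoothed: no prior is imposed on unseen pairs. In RFT/ZRFT they
  contribute 0 by default; `missing_value` substitutes a fixed penalty if
  the analyst prefers to punish pairs absent from the reference.
* **PMIRM diagonal.** Applied literally the PMI formula would put
  $-\log_2 p_{ii}$ on the diagonal; the package follows the stated
  convention that the PMIRM diagonal of observed features is zero, and
  records matrices accordingly.
* **Standardization statistics.** $\mu$ and $\sigma$ of the ZPMIRM are
  computed over the *defined off-diagonal* values, each unordered pair
  counted once, with the population (not sample) $\sigma$. The zeroed
  diagonal is a convention artifact, not data, so it is excluded from the
  statistics but is still mapped through $(v - \mu)/\sigma$. A profile
  whose defined off-diagonal values are all equal ($\sigma = 0$) is
  reported as a hard error naming the degenerate profile.
* **Mean denominator.** $\mu$ in RFT/ZRFT averages over all $D^2$ cells by
  default (`mean_over = "all"`), keeping the denominator fixed so scores
  are comparable across queries; `mean_over = "defined"` divides by the
  number of reference-defined cells instead.
* **Exclusive-pair mining** uses closed PMI intervals $[lo, hi]$, and two
  readings of "not present in other databases": in-range elsewhere blocks
  exclusivity (default), or any defined value elsewhere blocks it
  (`mode = "absent"`).
* **Counts** are stored as doubles: integer-exact to $2^{53}$, far beyond
  the $|S| \sim 10^8$ scale of public databases. Log base is 2 throughout.

## Fitting and scoring

```{r worked}
x <- fpset(rbind(c(1, 1, 0), c(1, 1, 0), c(1, 0, 1), c(0, 0, 1)),
           fingerprint_spec("custom", length = 3))
fit <- interrelation(x, label = "toy")
summary(fit)
coef(fit, "pmirm")
predict(fit, fpset(c(1, 1, 0), x$spec))
```

The three-feature set above is the package's worked example: its CORM,
COPRM, PMI values $\{+0.415, -0.585\}$, Z-scores $\{+1, -1\}$ and the
singleton scores printed here are all reproduced exactly by hand
computation in the test suite.

## The chemistry path

Real compounds enter through SMILES or SDF files.  Standardization is a
declared, deterministic contract executed by Open Babel: keep the largest
organic fragment, neutralize charges where valence permits, strip
stereochemistry and isotopes, and *no* tautomer canonicalization (no
defensible canonical rule was available, and the operation is not
idempotent across toolkits). Duplicates are collapsed by the InChIKey of
the standardized structure; parse, standardization and encoding failures
are carried in a rejects report rather than silently dropped. Fingerprints
are MACCS structure keys (166 semantic bits — the toolkit's padded storage
bits are not part of the matrix dimension) and ECFP4/ECFP6 hashed circular
fingerprints folded to 1024 bits by OR-ing hash positions modulo the
length. The PubChem 881-bit key is supported as a declared feature space
for pre-encoded FPS input, but is not generated in-package because the
installed toolkit does not define those 881 substructure patterns.
Relation-matrix containers embed the toolkit version and loading refuses a
mismatched container outright: hashed-fingerprint bit semantics are not
stable across toolkit versions, so silently mixing reference profiles
would corrupt scores.

## What the synthetic generator emulates — and what it does not

`synthetic_design()` draws binary vectors with independent Bernoulli
marginals $p_i$ and a chosen set of feature-disjoint *planted pairs*, each
drawn from the exact 2×2 joint with both-on probability $e\,p_i p_j$. The
population PMI of a planted pair is then $\log_2 e$ by construction, which
gives every estimator in the package a known ground truth; restricting
plants to disjoint pairs keeps the joint distribution exactly specifiable
without copula machinery. `scramble_columns()` permutes every feature
column independently, preserving marginals exactly while destroying all
pairwise structure — the surrogate for an "incoherent" compound set.

Real fingerprints violate these assumptions in instructive ways: bits are
not independent outside planted pairs (nested circular substructures are
strongly hierarchical), marginals are heavy-tailed rather than uniform,
and the co-occurrence structure of real chemistry is dense rather than
sparse. Passing tests on synthetic data therefore demonstrate estimator
correctness (the right quantity is computed, with the advertised
precision), not that any particular chemical conclusion transfers to a
given database.

Study conditions used by the test suite and the acceptance script, chosen
once as representative desk-scale conditions:

* *Parameter recovery*: $p = 0.2$, $e \in \{0.5, 1, 2, 4\}$, $n = 50{,}000$
  compounds, 20 seeds; at those sizes binomial error propagation puts the
  PMI standard error near 0.02, so the median absolute error bound of 0.05
  is comfortable but not vacuous.
* *End-to-end classification*: $D = 64$ bits at marginal $p = 0.3$ with 24
  disjoint pairs planted at $e = 3$ (close to the feasibility bound
  $e \le 1/p$), reference $|S'| = 4000$, query sets of 250 coherent (ES
  surrogate) and 250 column-scrambled (HS surrogate) compounds, 20 seeds.
  A normal approximation to the per-compound count of on-planted-pairs
  (Binomial(24, 0.27) vs Binomial(24, 0.09)) predicts AUC ≈ 0.95 before
  any simulation; the suite requires median AUC > 0.9.
* *Database-protocol numbers* (exhaustive 12,497,500 pairs from 5000
  sampled compounds; Jaccard overlap from published unique-compound
  counts) are recomputed from their defining formulas.

## Classification layer

Per-compound ZRFT scores (or any external score column such as SAScore,
SYBA or a random-forest probability, read as plain numbers) are evaluated
with ES — easy to synthesize — as the positive class and the rule
`score >= threshold => ES`; higher ZRFT means more reference-like feature
pairings, and in synthetic-accessibility work the reference profile is
built from synthesizable chemistry. AUC uses the rank (Mann–Whitney)
identity, which equals the trapezoidal ROC area with ties counted 0.5.
The Youden threshold maximizes $SN + SP - 1$ over midpoints of consecutive
distinct scores plus $\pm\infty$, ties broken toward the lowest threshold
— a deterministic rule that survives monotone score transforms (the
induced classification is invariant even though midpoint values move).
Multi-instance evaluation averages per-instance metrics arithmetically;
both a per-instance Youden policy and a fixed threshold are exposed
because averaged reports in the literature do not always state which was
used.

## Known limitations

* Tightness scores come with no significance calibration; they are
  comparative, not inferential.
* The standardization contract approximates, but is not identical to,
  pipelines built on other standardizers; InChIKey-based deduplication
  inherits InChI's normalization quirks.
* Exact reproduction of database-scale published statistics requires the
  original corpora (hundreds of millions of compounds), which are
  deliberately outside the package's inputs; the package reproduces the
  protocols and the desk-scale quantities.
* Dense $D \times D$ doubles cap practical fingerprint lengths around a
  few thousand bits — ample for 166/881/1024-bit features, not for
  unfolded hash spaces.
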