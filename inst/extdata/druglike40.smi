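# synthetic hand-written drug-like SMILES fixture (40 valid structures)
CC(=O)Oc1ccccc1C(=O)O aspirin_like_01
CC(=O)Nc1ccc(O)cc1 acetaminophen_like_02
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen_like_03
c1ccc2c(c1)cccn2 quinoline_04
c1ccc2[nH]ccc2c1 indole_05
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine_like_06
NC(=O)c1ccccc1 benzamide_07
Nc1ccc(cc1)S(N)(=O)=O sulfanilamide_08
OC(=O)c1ccccc1O salicylic_09
CN1CCC[C@H]1c1cccnc1 nicotine_like_10
Clc1ccc(cc1)C(c1ccccc1)N1CCCC1 clph_amine_11
COc1ccc2cc(ccc2c1)C(C)C(=O)O naproxen_like_12
CC(N)Cc1ccccc1 amphetamine_like_13
NCCc1ccc(O)c(O)c1 dopamine_like_14
OCCN1CCN(CC1)c1ccccn1 piperazine_15
Fc1ccc(cc1)C(=O)CCCN1CCC(O)CC1 haloperidol_frag_16
CC(=O)NCCc1c[nH]c2ccc(OC)cc12 melatonin_like_17
OC(=O)CCc1ccccc1 phenylpropanoic_18
Nc1ncnc2[nH]cnc12 adenine_19
O=c1ccn(c(=O)[nH]1)C uracil_me_20
CCOC(=O)c1ccccc1N ethyl_anthranilate_21
CSc1ccccc1 thioanisole_22
O=C(Nc1ccccc1)c1ccccc1 benzanilide_23
CN(C)CCOC(c1ccccc1)c1ccccc1 diphenhydramine_24
OCC1OC(O)C(O)C(O)C1O glucose_like_25
CC12CCC3c4ccc(O)cc4CCC3C1CCC2O estradiol_like_26
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1 atenolol_like_27
Clc1ccccc1Cl dichlorobenzene_28
Oc1ccc(cc1)C(c1ccc(O)cc1)(C)C bisphenol_29
COc1cc2c(cc1OC)CCN(C)C2 tetrahydroisoq_30
O=C1CCCCC1 cyclohexanone_31
c1ccc(cc1)c1ccccc1 biphenyl_32
c1ccsc1 thiophene_33
c1ccoc1 furan_34
CC(=O)C1CCC2C1(C)CCC1C2CCC2(C)C(O)CCC12 steroid_frag_35
N#Cc1ccccc1 benzonitrile_36
OC(=O)C(N)Cc1c[nH]cn1 histidine_37
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1 salbutamol_like_38
CCN(CC)CCNC(=O)c1ccc(N)cc1 procainamide_like_39
OC(=O)c1cc(O)c(O)c(O)c1 gallic_40
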