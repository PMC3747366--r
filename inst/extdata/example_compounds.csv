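id,smiles,label
methotrexate_like,Nc1nc2ncc(CNc3ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc3)nc2c(N)n1,1
quinolone_a,O=C(O)c1cn(C2CC2)c3cc(N4CCNCC4)c(F)cc3c1=O,1
flavone_a,O=c1cc(-c2ccccc2)oc3ccccc13,1
flavone_b,O=c1cc(-c2ccc(O)cc2)oc3cc(O)cc(O)c13,1
styryl_amide,O=C(Nc1ccccc1)C=Cc2ccccc2,1
sulfonamide_a,NS(=O)(=O)c1ccc(N)cc1,1
benzodiazepine_like,O=C1CN=C(c2ccccc2)c3cc(Cl)ccc3N1,-1
steroid_like,CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O,-1
tricyclic_a,C1Cc2ccccc2Sc3ccccc13,-1
alkaloid_a,CN1CCC23CCCCC2C1Cc4ccccc34,-1
biphenyl_a,c1ccc(-c2ccccc2)cc1,-1
pyridine_a,CCOC(=O)c1ccncc1,-1
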