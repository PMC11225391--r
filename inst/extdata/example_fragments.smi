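# example 1-site fragments for link: SMILES<TAB>id
C1C(*)C1	cyclopropyl
n1(*)ccncc1	pyrazinyl
c1ccc(*)cc1	phenyl
OC(*)	hydroxymethyl
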