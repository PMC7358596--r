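ligand_id,receptor_id,galpha_class,dg_ligand_kcal,dg_gdp_kcal,dg_gtp_kcal,bib_class,model_class
5-oxo-ETE,OXER1,Gi,-14.5,-896.5,-528.3,agonist,agonist
Testosterone,OXER1,Gi,-10.9,-663,-507.9,antagonist,antagonist
5-HETE,OXER1,Gi,-14.5,-710.8,-565.5,partial_agonist,partial_agonist
12-HpETE,OXER1,Gi,-14.2,-713.8,-521.4,partial_agonist,partial_agonist
15-HpETE,OXER1,Gi,-14.1,-758.3,-544,partial_agonist,partial_agonist
12-HETE,OXER1,Gi,-14.5,-717.7,-566.3,partial_agonist,partial_agonist
15-HETE,OXER1,Gi,-13.3,-723.8,-566.6,partial_agonist,partial_agonist
TC150,OXER1,Gi,-15.4,-657.3,-544.2,unknown,antagonist
TC151,OXER1,Gi,-16.1,-645.2,-541.1,unknown,antagonist
TC153,OXER1,Gi,-14.5,-635.2,-572.6,unknown,antagonist
B2,OXER1,Gi,-25.4,-665.2,-485.1,unknown,antagonist
B5,OXER1,Gi,-25.1,-736.2,-590.4,unknown,partial_agonist
Epicatechin,OXER1,Gi,-13,-642.8,-552.5,unknown,antagonist
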