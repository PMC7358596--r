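ligand_id,receptor_id,galpha_class,dg_ligand_kcal,dg_gdp_kcal,dg_gtp_kcal,bib_class,model_class
Ergotamine,serotonin,Go,-17.5,-1193.5,-368.5,agonist,agonist
Oxymetazoline,serotonin,Go,-9.9,-830.2,-369.7,agonist,agonist
Sumatriptan,serotonin,Go,-9.4,-993.4,-320.8,agonist,agonist
Zolmitriptan,serotonin,Go,-10.5,-886.7,-398,agonist,agonist
Dextromethorphan,serotonin,Go,-11.1,-713.8,-376.4,partial_agonist,partial_agonist
Ziprasidone,serotonin,Go,-9.1,-692.5,-338,partial_agonist,antagonist
Asenapine,serotonin,Go,-8.9,-736.9,-380.2,partial_agonist,partial_agonist
Vortioxetine,serotonin,Go,-9.9,-701.9,-356.6,partial_agonist,antagonist
Metitepine,serotonin,Go,-10.4,-618,-362.7,antagonist,antagonist
Yohimbine,serotonin,Go,-10.2,-588.9,-312.2,antagonist,antagonist
Metergoline,serotonin,Go,-12.2,-542.6,-302.9,antagonist,antagonist
Isamoltane,serotonin,Go,-9.9,-523.3,-325.6,antagonist,antagonist
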