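ligand_id,receptor_id,galpha_class,dg_ligand_kcal,dg_gdp_kcal,dg_gtp_kcal,bib_class,model_class
Dopamine,dopamine-D3,Gi,-9.6,-779.9,-349,agonist,partial_agonist
Quinpirole,dopamine-D3,Gi,-9.8,-719.7,-378.8,agonist,partial_agonist
5OH-DPAT,dopamine-D3,Gi,-8.8,-864,-348.4,agonist,agonist
Pergolide,dopamine-D3,Gi,-9.4,-780.2,-400.7,agonist,partial_agonist
Captodiame,dopamine-D3,Gi,-10,-793,-311,agonist,partial_agonist
Apomorphine,dopamine-D3,Gi,-6.7,-804.9,-376.3,agonist,agonist
Aripiprazole,dopamine-D3,Gi,-16.9,-761.1,-327.7,partial_agonist,partial_agonist
Cariprazine,dopamine-D3,Gi,-11.3,-763.6,-388.8,partial_agonist,partial_agonist
Buspirone,dopamine-D3,Gi,-11.1,-772.3,-334.5,partial_agonist,partial_agonist
Pardoprunox,dopamine-D3,Gi,-5.2,-787.1,-349.4,partial_agonist,partial_agonist
Nafadotride,dopamine-D3,Gi,-8.5,-652.5,-373.3,antagonist,antagonist
Raclopride,dopamine-D3,Gi,-10.7,-685.4,-330,antagonist,antagonist
Haloperidol,dopamine-D3,Gi,-10.5,-683,-321.6,antagonist,antagonist
Amisulpride,dopamine-D3,Gi,-10.2,-686,-396.5,antagonist,antagonist
Cyproheptadine,dopamine-D3,Gi,-6.1,-690.8,-285.7,antagonist,antagonist
Risperidone,dopamine-D3,Gi,-12.1,-682.7,-370.7,antagonist,antagonist
Acetylmorphone,mu-opioid,Gi,-9.6,-855.2,-615.4,agonist,agonist
Benzhydrocodone,mu-opioid,Gi,-10.9,-821.3,-616.9,agonist,agonist
Heroin,mu-opioid,Gi,-12.4,-1045.4,-620.7,agonist,agonist
Methadone,mu-opioid,Gi,-8.7,-902.4,-561.6,agonist,agonist
Nicocodeine,mu-opioid,Gi,-12.0,-855.1,-526.4,agonist,agonist
Butorphanol,mu-opioid,Gi,-10.2,-769.8,-540.4,partial_agonist,partial_agonist
Ciprefadol,mu-opioid,Gi,-9.0,-773.2,-656.4,partial_agonist,partial_agonist
Cyclorphan,mu-opioid,Gi,-8.9,-779.8,-669.2,partial_agonist,partial_agonist
Ketorfanol,mu-opioid,Gi,-9.0,-778.6,-638.6,partial_agonist,partial_agonist
Xorphanol,mu-opioid,Gi,-9.0,-783.3,-674.4,partial_agonist,partial_agonist
Moxazocine,mu-opioid,Gi,-8.5,-799.0,-629.7,partial_agonist,partial_agonist
Nalbuphine,mu-opioid,Gi,-10.1,-780.7,-589.9,partial_agonist,partial_agonist
Nalmefene,mu-opioid,Gi,-9.8,-697.2,-650.7,antagonist,antagonist
Nalodeine,mu-opioid,Gi,-9.7,-703.1,-594.9,antagonist,antagonist
Nalorphine,mu-opioid,Gi,-10.7,-699.8,-651.2,antagonist,antagonist
Naloxone,mu-opioid,Gi,-9.3,-698.4,-575.7,antagonist,antagonist
Naltrexone,mu-opioid,Gi,-9.9,-691.3,-619.2,antagonist,antagonist
Levallorphan,mu-opioid,Gi,-8.8,-698.4,-584.0,antagonist,antagonist
DAMGO,mu-opioid,Gi,-16.3,-861.0,-582.0,agonist,agonist
ADO,adenosine-A1,Gi,-8.7,-1079.6,-646.1,agonist,agonist
CCPA,adenosine-A1,Gi,-12.5,-1062.6,-659.9,agonist,agonist
CPA,adenosine-A1,Gi,-11.9,-1009.9,-563.6,agonist,agonist
N(6)-Cyclohexyladenosine,adenosine-A1,Gi,-11.4,-1099.7,-679.7,agonist,agonist
Tecadenoson,adenosine-A1,Gi,-11.9,-888.4,-585.8,agonist,agonist
Selodenoson,adenosine-A1,Gi,-13,-990.8,-638.6,agonist,agonist
Caffeine,adenosine-A1,Gi,-6.3,-631.4,-372.6,antagonist,antagonist
Bamifylline,adenosine-A1,Gi,-12.1,-674.2,-553.3,antagonist,antagonist
CGS-15943,adenosine-A1,Gi,-9.2,-531.9,-356.2,antagonist,antagonist
Theophylline,adenosine-A1,Gi,-6.1,-547.1,-469,antagonist,antagonist
Retinal,rhodopsin,Gi,-9.9,-972.9,-359.2,agonist,antagonist
Halothane,rhodopsin,Gi,-4.2,-377.7,-335.9,antagonist,antagonist
Palmitic Acid,rhodopsin,Gi,-9.9,-447.7,-356.6,antagonist,antagonist
Zoledronic Acid,rhodopsin,Gi,-10.7,-442.1,-326.3,antagonist,antagonist
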