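ligand_id,receptor_id,galpha_class,dg_ligand_kcal,dg_gdp_kcal,dg_gtp_kcal,bib_class,model_class
Prucalopride,5-HT1B,unknown,-12.323,X,X,agonist,non_interactor
Prucalopride,5-HT4,Gs,-13.566,-1065.67,-690.85,agonist,agonist
Lofexidine,alphaB2-adrenergic,unknown,-10.619,X,X,agonist,non_interactor
Lofexidine,alpha2A-adrenergic,Gi,-8.933,-1061.31,-473.26,agonist,agonist
Latanoprostene,PTGDR2,unknown,-20.039,X,X,agonist,non_interactor
Latanoprostene,prostaglandin-F-R,Gq,-19.614,-1029.24,-551.30,agonist,agonist
Naldemedine,mu-opioid,Gi,-15.576,-657.09,-594.69,antagonist,antagonist
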