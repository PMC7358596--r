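ligand_id,receptor_id,galpha_class,dg_ligand_kcal,dg_gdp_kcal,dg_gtp_kcal,bib_class,model_class
Bitolterol,beta2-adrenergic,Gs,-16.7,-910.6,-700.1,agonist,agonist
Formoterol,beta2-adrenergic,Gs,-13.4,-877.5,-700.9,agonist,agonist
Isoprenaline,beta2-adrenergic,Gs,-10.8,-933,-699,agonist,agonist
Levosalbutamol,beta2-adrenergic,Gs,-12,-890.7,-695,agonist,agonist
Orciprenaline,beta2-adrenergic,Gs,-11.1,-892.3,-696,agonist,agonist
Ritodrine,beta2-adrenergic,Gs,-11.8,-924.4,-704.4,agonist,agonist
Salbutamol,beta2-adrenergic,Gs,-11.4,-961.1,-691.3,agonist,agonist
Salmeterol,beta2-adrenergic,Gs,-16.8,-956.9,-695.2,agonist,agonist
Terbutaline,beta2-adrenergic,Gs,-11.2,-853.1,-697,agonist,agonist
"ICI118,551",beta2-adrenergic,Gs,-10.6,-725.1,-707.5,antagonist,partial_agonist
Butoxamine,beta2-adrenergic,Gs,-12.1,-706.4,-696.6,antagonist,partial_agonist
Propranolol,beta2-adrenergic,Gs,-11.6,-719.7,-706.6,antagonist,partial_agonist
BI-167107,beta2-adrenergic,Gs,-15.4,-971.3,-705.6,agonist,agonist
Prostaglandin-E2,prostaglandin-DR2,Gs,-14.3,-1079,-475.6,agonist,agonist
Prostaglandin-F2a,prostaglandin-DR2,Gs,-14.7,-1091.9,-431.3,agonist,agonist
Prostacyclin,prostaglandin-DR2,Gs,-14.6,-1003.2,-455,agonist,agonist
Fevipiprant,prostaglandin-DR2,Gs,-14.9,-462.2,-412.2,antagonist,antagonist
Ramatroban,prostaglandin-DR2,Gs,-15.4,-422.1,-416.4,antagonist,antagonist
Setipiprant,prostaglandin-DR2,Gs,-14.9,-442.8,-418,antagonist,antagonist
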