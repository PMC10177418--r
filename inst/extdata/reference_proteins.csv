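protein,mw_kda,category,fractions
Ceruloplasmin,122.13,other,1
Complement factor H,139.01,other,1
Plasminogen,90.51,other,2
Complement component C6,104.72,other,2
Serotransferrin,77.01,glomerular_indicator,3
Kininogen,71.91,other,3
Albumin,69.23,glomerular_indicator,4;5;6
Complement component C9,63.13,other,4
Hemopexin,51.64,other,5;6
Antithrombin-III,52.57,other,5;6
Pigment epithelium-derived factor,46.28,other,6;7
Vitamin D-binding protein,52.88,other,6;7
Apolipoprotein A-IV,45.34,other,6;7
Protein AMBP,38.97,tubular_indicator,8;9
Zinc-alpha-2-glycoprotein,34.24,other,8
Beta-2-glycoprotein,38.27,other,8
Apolipoprotein A-I,30.76,other,9;10;11
Complement factor D,27.02,other,10
Immunoglobulin kappa light chain,23.36,overload_indicator,10;11
Immunoglobulin light chain dimer,46.00,overload_indicator,
Prostaglandin-H2 D-isomerase,21.02,other,10
Retinol-binding protein 4,22.99,tubular_indicator,11;12;13
Neutrophil gelatinase-associated lipocalin,22.57,tubular_indicator,11;12
Tetranectin,22.52,other,12
Myoglobin,17.17,overload_indicator,13
Transthyretin,15.88,other,13
Cystatin C,15.79,tubular_indicator,14;15
Lysozyme C,16.53,overload_indicator,14
Hemoglobin subunit beta,15.99,overload_indicator,14
Beta-2-microglobulin,13.71,tubular_indicator,15
Cystatin M,16.50,other,15
Ovalbumin,44.29,overload_indicator,
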