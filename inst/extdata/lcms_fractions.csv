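fraction,protein,psm,mw_kda
1,Ceruloplasmin,28,122.13
1,Complement factor H,17,139.01
2,Plasminogen,29,90.51
2,Complement component C6,17,104.72
2,Complement component C7,12,93.46
2,Inter-alpha-trypsin inhibitor heavy chain H,11,103.29
3,Serotransferrin,550,77.01
3,Coagulation factor XIII B chain,104,75.46
3,Kininogen,65,71.91
3,Afamin,34,69.02
3,Protein disulfide-isomerase A4,18,72.89
4,Albumin,1073,69.23
4,Complement component C9,55,63.13
5,Albumin,2756,69.23
5,Hemopexin,308,51.64
5,Antithrombin-III,104,52.57
6,Albumin,1135,69.23
6,Pigment epithelium-derived factor,411,46.28
6,Vitamin D-binding protein,295,52.88
6,Hemopexin,147,51.64
6,Apolipoprotein A-IV,140,45.34
6,Antithrombin-III,135,52.57
7,Apolipoprotein A-IV,471,45.34
7,Pigment epithelium-derived factor,163,46.28
7,Vitamin D-binding protein,124,52.88
7,EGF-containing fibulin-like extracellular matrix protein 1,22,54.60
8,Protein AMBP,276,38.97
8,Zinc-alpha-2-glycoprotein,62,34.24
8,Beta-2-glycoprotein,51,38.27
8,Insulin-like growth factor-binding protein 2,22,34.79
9,Protein AMBP,933,38.97
9,CD-5 antigen like,42,38.06
9,Mimecan,31,33.90
9,Apolipoprotein A-I,29,30.76
9,Corticotropin-releasing factor-binding protein,28,36.12
10,Complement factor D,532,27.02
10,Apolipoprotein A-I,438,30.76
10,Immunoglobulin kappa light chain,280,23.36
10,Phosphatidylethanolamine-binding protein 4,130,25.72
10,Prostaglandin-H2 D-isomerase,87,21.02
11,Immunoglobulin kappa light chain,499,23.36
11,Retinol-binding protein 4,132,22.99
11,Apolipoprotein A-I,58,30.76
11,Neutrophil gelatinase-associated lipocalin,56,22.57
12,Retinol-binding protein 4,777,22.99
12,Protein FAM3C,56,24.67
12,Tetranectin,27,22.52
12,Neutrophil gelatinase-associated lipocalin,19,22.57
12,Transgelin,18,22.60
12,Ganglioside GM2 activator,16,20.83
12,Metalloproteinase inhibitor 2,16,24.38
13,Retinol-binding protein 4,234,22.99
13,Retinoic acid receptor responder protein 2,96,18.61
13,Myoglobin,82,17.17
13,Peptidyl-prolyl cis-trans isomerase A,52,18.00
13,Transthyretin,33,15.88
14,Cystatin C,608,15.79
14,Lysozyme C,288,16.53
14,"Fatty acid-binding protein, adipocyte",107,14.71
14,Profilin-1,51,15.05
14,"Fatty acid-binding protein, liver",38,14.20
14,Hemoglobin subunit beta,27,15.99
15,Beta-2-microglobulin,251,13.71
15,Cystatin C,82,15.79
15,Cystatin M,34,16.50
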