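group,icd10,n_all,n_tubular_mixed,n_pure_glomerular
TOTAL,,300,204,96
Hematologic lymphoid disorders,,117,91,26
Multiple myeloma,C90.0,112,87,25
MGUS,D47.2,4,3,1
Follicular lymphoma,C82.9,1,1,0
Renal disorders,,133,83,50
Chronic kidney disease,N18.x,59,37,22
Kidney transplant status,Z94.0,18,12,6
Glomerular diseases,N03.x-N06.x,36,20,16
Acute kidney injury,N17.x,9,7,2
Unspecified kidney failure,N19.x,6,2,4
Diabetes mellitus with renal complications,E10.2;E11.2,3,3,0
Other disorders of kidney and ureter,N28.x,2,2,0
Other potentially relevant disorders,,16,9,7
Wegener granulomatosis,M31.3,2,0,2
Sjogren syndrome,M35.0,1,1,0
Malignant neoplasms,Cx,9,2,7
Diseases of the circulatory system,Ix,5,5,0
Uninformative or missing codes,,33,22,11
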