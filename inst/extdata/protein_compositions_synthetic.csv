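# Synthetic/representative residue compositions (editable fixtures).
# beta_lg: approximate mature bovine beta-lactoglobulin (162 residues).
# alpha_la: approximate mature bovine alpha-lactalbumin (123 residues).
# glm_protein: representative mixed bactopeptone + meat-extract protein
#   pool (stand-in; the real media compositions are not published).
protein,ala,arg,asn,asp,cys,gln,glu,gly,his,ile,leu,lys,met,phe,pro,ser,thr,trp,tyr,val
beta_lg,14,3,5,11,5,9,16,3,2,10,22,15,4,4,8,7,8,2,4,10
alpha_la,3,1,8,13,8,6,7,6,3,8,13,12,1,4,2,7,7,4,4,6
glm_protein,28,18,13,18,4,14,30,24,8,14,26,26,8,12,16,14,14,3,10,16
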