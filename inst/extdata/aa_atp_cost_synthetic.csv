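# Synthetic/representative ATP-equivalent biosynthesis cost per amino-acid
# residue (mol ATP per mol residue), in the style of published
# high-energy-phosphate-bond accounting of amino-acid biosynthesis.
# Editable: swap in your organism-specific cost table.
aa,cost
ala,11.7
arg,27.3
asn,14.7
asp,12.7
cys,24.7
gln,16.3
glu,15.3
gly,11.7
his,38.3
ile,32.3
leu,27.3
lys,30.3
met,34.3
phe,52.0
pro,20.3
ser,11.7
thr,18.7
trp,74.3
tyr,50.0
val,23.3
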