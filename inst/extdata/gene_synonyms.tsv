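synonym	canonical
ND1	nad1
ND2	nad2
ND3	nad3
ND4	nad4
ND4L	nad4L
ND5	nad5
ND6	nad6
NAD1	nad1
NAD2	nad2
NAD3	nad3
NAD4	nad4
NAD4L	nad4L
NAD5	nad5
NAD6	nad6
NADH1	nad1
NADH2	nad2
NADH3	nad3
NADH4	nad4
NADH4L	nad4L
NADH5	nad5
NADH6	nad6
COX1	cox1
COX2	cox2
COX3	cox3
COXI	cox1
COXII	cox2
COXIII	cox3
COI	cox1
COII	cox2
COIII	cox3
CO1	cox1
CO2	cox2
CO3	cox3
COB	cytb
CYTB	cytb
CYB	cytb
ATP6	atp6
ATP8	atp8
ATPASE6	atp6
ATPASE8	atp8
12S	rrnS
16S	rrnL
12S-RRNA	rrnS
16S-RRNA	rrnL
S-RRNA	rrnS
L-RRNA	rrnL
RRN12	rrnS
RRN16	rrnL
SSU	rrnS
LSU	rrnL
D-LOOP	CR
DLOOP	CR
CONTROL-REGION	CR
CONTROL_REGION	CR
AT-RICH-REGION	CR
CONTROLREGION	CR
AT-RICHREGION	CR
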