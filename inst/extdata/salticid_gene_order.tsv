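gene	strand
cox1	J
cox2	J
trnK	J
trnD	J
atp8	J
atp6	J
cox3	J
trnG	J
nad3	J
trnA	J
trnR	J
trnN	J
trnL2	J
trnS1	J
trnE	J
trnF	N
nad5	N
trnH	N
nad4	N
nad4L	N
trnT	J
trnP	N
nad6	J
cytb	J
trnS2	J
nad1	N
trnL1	N
rrnL	N
trnV	N
rrnS	N
trnQ	N
CR	J
trnM	J
nad2	J
trnW	J
trnC	N
trnY	N
trnI	N
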