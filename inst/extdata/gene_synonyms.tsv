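synonym	canonical
cox1	cox1
coxi	cox1
coi	cox1
co1	cox1
cox2	cox2
coxii	cox2
coii	cox2
co2	cox2
cox3	cox3
coxiii	cox3
coiii	cox3
co3	cox3
cytochromecoxidasesubunit1	cox1
cytochromecoxidasesubunit2	cox2
cytochromecoxidasesubunit3	cox3
cytochromecoxidasesubuniti	cox1
cytochromecoxidasesubunitii	cox2
cytochromecoxidasesubunitiii	cox3
cytb	cytb
cob	cytb
cyb	cytb
cytochromeb	cytb
nad1	nad1
nd1	nad1
nadh1	nad1
nadhdehydrogenasesubunit1	nad1
nad2	nad2
nd2	nad2
nadh2	nad2
nadhdehydrogenasesubunit2	nad2
nad3	nad3
nd3	nad3
nadh3	nad3
nadhdehydrogenasesubunit3	nad3
nad4	nad4
nd4	nad4
nadh4	nad4
nadhdehydrogenasesubunit4	nad4
nad4l	nad4L
nd4l	nad4L
nadh4l	nad4L
nadhdehydrogenasesubunit4l	nad4L
nad5	nad5
nd5	nad5
nadh5	nad5
nadhdehydrogenasesubunit5	nad5
nad6	nad6
nd6	nad6
nadh6	nad6
nadhdehydrogenasesubunit6	nad6
atp6	atp6
atpase6	atp6
atpsynthasef0subunit6	atp6
atp8	atp8
atpase8	atp8
atpsynthasef0subunit8	atp8
rrns	rrnS
12s	rrnS
12srrna	rrnS
12sribosomalrna	rrnS
srrna	rrnS
smallsubunitribosomalrna	rrnS
rrnl	rrnL
16s	rrnL
16srrna	rrnL
16sribosomalrna	rrnL
lrrna	rrnL
largesubunitribosomalrna	rrnL
cr	CR
dloop	CR
controlregion	CR
atrichregion	CR
putativecontrolregion	CR
trna	trnA
trnaala	trnA
trnr	trnR
trnaarg	trnR
trnn	trnN
trnaasn	trnN
trnd	trnD
trnaasp	trnD
trnc	trnC
trnacys	trnC
trnq	trnQ
trnagln	trnQ
trne	trnE
trnaglu	trnE
trng	trnG
trnagly	trnG
trnh	trnH
trnahis	trnH
trni	trnI
trnaile	trnI
trnk	trnK
trnalys	trnK
trnm	trnM
trnamet	trnM
trnf	trnF
trnaphe	trnF
trnp	trnP
trnapro	trnP
trnt	trnT
trnathr	trnT
trnw	trnW
trnatrp	trnW
trny	trnY
trnatyr	trnY
trnv	trnV
trnaval	trnV
trnl1	trnL1
trnlcun	trnL1
trnaleucun	trnL1
trnaleutag	trnL1
trnl2	trnL2
trnluur	trnL2
trnaleuuur	trnL2
trnaleutaa	trnL2
trns1	trnS1
trnsagn	trnS1
trnaseragn	trnS1
trnasergct	trnS1
trnasergcu	trnS1
trns2	trnS2
trnsucn	trnS2
trnaserucn	trnS2
trnasertga	trnS2
trnaseruga	trnS2
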