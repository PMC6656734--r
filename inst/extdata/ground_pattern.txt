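# Pancrustacean ancestral mitochondrial gene order (37 genes), anchored at
# cox1, read on the forward strand; "-" marks genes encoded on the minus
# strand. Editable: replace to use a different reference arrangement.
cox1
trnL2
cox2
trnK
trnD
atp8
atp6
cox3
trnG
nad3
trnA
trnR
trnN
trnS1
trnE
-trnF
-nad5
-trnH
-nad4
-nad4l
trnT
-trnP
nad6
cob
trnS2
-nad1
-trnL1
-rrnL
-trnV
-rrnS
trnI
-trnQ
trnM
nad2
trnW
-trnC
-trnY
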