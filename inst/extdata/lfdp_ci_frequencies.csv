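marker,rank,ci
trnH-psbA,species,0.98
rbcLa,species,0.937
matK,species,1
trnH-psbA,genus,1
rbcLa,genus,1
matK,genus,1
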