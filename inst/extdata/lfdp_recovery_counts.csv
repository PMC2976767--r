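level,column,successes,total
species,trnH-psbA,131,143
species,rbcLa,129,143
species,matK,100,143
genus,trnH-psbA,106,108
genus,rbcLa,106,108
genus,matK,76,108
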