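411dc1660d66883bcc90488bc67a8efe  JTT.dat
424df387a5b7229ce07c1b1e204f051c  WAG.dat
74b254e820fbbfa8cecbe8ac4e98360c  Dayhoff.dat
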