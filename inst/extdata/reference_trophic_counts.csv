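level,class,count
L1C,Low,75690
L1C,Medium,7044
L1C,High,1301
L1C,Hypereutrophic,403
L2A,Low,4998
L2A,Medium,4418
L2A,High,329
L2A,Hypereutrophic,16
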