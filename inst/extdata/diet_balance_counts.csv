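role,arm,sex,count
proband,blue,male,327
proband,blue,female,479
proband,green,male,349
proband,green,female,456
familiar,blue,male,13
familiar,blue,female,68
familiar,green,male,5
familiar,green,female,58
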