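# Example run configuration: chromosome 6 (Hg19)
name=chr6
length=171115067
centromere=58780166-61880166
segments=7
reps=10000
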