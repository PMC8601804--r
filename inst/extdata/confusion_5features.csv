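class,hunger,sleep,discomfort
hunger,178,2,6
sleep,4,120,5
discomfort,5,1,180
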