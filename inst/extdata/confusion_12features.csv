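class,hunger,sleep,discomfort
hunger,168,3,15
sleep,7,113,9
discomfort,7,1,178
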