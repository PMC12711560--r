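group,share
children,0.34
women,0.32
men,0.34
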