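method,n
none,3237
traditional,402
modern,3208
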