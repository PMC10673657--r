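>tasiARF_syn1 synthetic 21-nt tasiARF stand-in payload (not a natural sequence)
TTCGGTACCATTAAGCGGACT
>tasiARF_syn2 synthetic 21-nt tasiARF stand-in payload (not a natural sequence)
GATTCACGCTAAGGTTCCAGT
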