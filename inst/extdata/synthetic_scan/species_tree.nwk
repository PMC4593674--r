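(((dolphin:0.07,whale:0.07):0.25,hippo:0.3):0.1,((pig:0.3,camel:0.3):0.15,cow:0.35):0.05);
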