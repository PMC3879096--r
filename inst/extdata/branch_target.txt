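# block all flux through the C-branch export
1 R5 >= 1
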