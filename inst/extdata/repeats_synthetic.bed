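chr19	57867908	57868909	synthetic_repeat_1
chrX	46359036	46360037	synthetic_repeat_2
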