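permittivity,peak_nm
80,485.2
17.5,433.7
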