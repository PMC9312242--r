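stage	count
synthesized	200
clear_bands	191
polymorphic	152
selected	29
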