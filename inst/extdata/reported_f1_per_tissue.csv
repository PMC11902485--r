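tissue,f1
CSF,0.9528
GM,0.9203
WM,0.9034
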