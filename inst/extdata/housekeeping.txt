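ABCF1
DNAJC14
ERCC3
G6PD
GUSB
MRPL19
OAZ1
POLR2A
SDHA
TBP
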