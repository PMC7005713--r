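protein	his_resno	note
HK853	260	phosphorylatable His260 of Thermotoga maritima HK853
EnvZ-HAMP-DHp	243	E. coli EnvZ phosphoacceptor His243
EnvZ-DHp	243	E. coli EnvZ phosphoacceptor His243
EnvZ-chimera	243	EnvZ numbering retained in the chimeric construct
EnvZ-HAMP-Af1503	243	EnvZ numbering retained in the chimeric construct
CpxA	248	E. coli CpxA phosphoacceptor His248
VicK	NA	supply from the deposition when running coordinate mode
WalK	NA	supply from the deposition when running coordinate mode
PhoR-DHp	NA	supply from the deposition when running coordinate mode
ERS1-DHp	NA	supply from the deposition when running coordinate mode
RetS-DHp-CA	NA	supply from the deposition when running coordinate mode
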