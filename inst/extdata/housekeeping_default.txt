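# Default housekeeping gene list (HGNC symbols): widely used constitutively
# expressed genes for anchoring the expressed component's initial EM values.
# Override with your own list when the expression matrix uses other IDs.
ACTB
GAPDH
B2M
TUBB
TBP
PPIA
RPL13A
RPLP0
RPS18
RPL37A
SDHA
HPRT1
PGK1
GUSB
YWHAZ
UBC
HMBS
TFRC
POLR2A
EEF1A1
PSMB2
PSMB4
RAB7A
REEP5
VCP
VPS29
CHMP2A
EMC7
GPI
SNRPD3
C1orf43
OAZ1
ATP5F1
PGAM1
ALDOA
LDHA
ENO1
PPIB
CANX
CALR
HSP90AB1
HSPA8
EIF4A2
NACA
RPL8
RPL11
RPS3
RPS5
RPS13
RPL32
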