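# Frozen snapshot of a curated human DNA-repair gene inventory.
# One current HGNC symbol per line. The live inventory this snapshot derives
# from is revised over time; this copy is shipped unchanged for reproducibility.
# Base excision repair (BER)
UNG
SMUG1
MBD4
TDG
OGG1
MUTYH
NTHL1
MPG
NEIL1
NEIL2
NEIL3
APEX1
APEX2
LIG3
XRCC1
PNKP
APLF
PARP1
PARP2
PARP3
# Direct reversal of damage
MGMT
ALKBH2
ALKBH3
# Mismatch excision repair (MMR)
MSH2
MSH3
MSH6
MLH1
PMS1
PMS2
MSH4
MSH5
MLH3
PMS2P3
# Nucleotide excision repair (NER)
XPC
RAD23B
RAD23A
CETN2
RAD4
DDB1
DDB2
RPA1
RPA2
RPA3
ERCC3
ERCC2
GTF2H1
GTF2H2
GTF2H3
GTF2H4
GTF2H5
CDK7
CCNH
MNAT1
ERCC5
ERCC1
ERCC4
LIG1
ERCC8
ERCC6
UVSSA
XAB2
MMS19
# Homologous recombination
RAD51
RAD51B
RAD51C
RAD51D
DMC1
XRCC2
XRCC3
RAD52
RAD54L
RAD54B
BRCA1
BARD1
ABRAXAS1
PAXIP1
SMC5
SMC6
SHLD1
SHLD2
SHLD3
SEM1
RAD50
MRE11
NBN
RBBP8
MUS81
EME1
EME2
SLX1A
SLX4
GEN1
BRCA2
PALB2
DSS1
RAD51AP1
SPIDR
SWI5
SWSAP1
ZSWIM7
# Fanconi anemia
FANCA
FANCB
FANCC
BRIP1
FANCD2
FANCE
FANCF
FANCG
FANCI
FANCL
FANCM
FAAP20
FAAP24
FAAP100
UBE2T
XRCC9
# Non-homologous end-joining
XRCC6
XRCC5
PRKDC
LIG4
XRCC4
DCLRE1C
NHEJ1
PAXX
MRI
# Modulation of nucleotide pools
NUDT1
RRM2B
NT5C3A
DUT
# DNA polymerases (catalytic subunits)
POLB
POLG
POLD1
POLE
PCNA
REV3L
MAD2L2
REV1
POLH
POLI
POLQ
POLK
POLL
POLM
POLN
PRIMPOL
# Editing and processing nucleases
FEN1
FAN1
TREX1
TREX2
EXO1
EXO5
APTX
SPO11
ENDOV
DNA2
# Ubiquitination and modification
UBE2A
UBE2B
RAD18
UBE2V2
UBE2N
SHPRH
HLTF
RNF168
SPRTN
RNF8
RNF4
PIAS1
PIAS4
UBE2I
# Chromatin structure and modification
H2AX
CHAF1A
SETMAR
ATRX
# Genes defective in diseases with sensitivity to DNA damage
BLM
RMI1
RMI2
TOP3A
TOP3B
WRN
RECQL4
ATM
MPLKIP
DCLRE1A
DCLRE1B
# Other conserved DNA damage response genes
RPA4
PRPF19
RECQL
RECQL5
HELQ
RDM1
NABP2
ATR
ATRIP
MDC1
RAD1
RAD9A
HUS1
RAD17
CHEK1
CHEK2
TP53
TP53BP1
RIF1
TOPBP1
CLK2
PER1
# Other identified genes with known or suspected DNA repair function
DNTT
EYA1
EYA2
EYA3
EYA4
LIG3AS1
APOBEC3G
NEIL2P1
TDP1
TDP2
CCNO
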