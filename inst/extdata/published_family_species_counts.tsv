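# Published family-by-species membrane-bound transcription factor counts for
# the 14 plant proteomes of the reference genome-wide survey (52 TF families).
family	Cr	Pp	Pa	Bd	Os	Sb	Zm	Gm	Mt	Gr	Sl	Pt	At	Vv
AP2	4	0	0	1	1	0	0	1	1	0	0	0	1	2
ARF	0	0	3	1	0	0	2	2	0	2	0	1	0	0
ARR-B	0	0	0	0	0	0	0	1	0	1	0	1	0	1
B3	0	4	0	3	2	1	0	1	2	1	0	0	2	2
BBR-BPC	0	0	1	0	0	0	0	0	0	0	0	1	0	0
BES1	0	1	1	0	0	0	1	1	0	1	0	1	0	0
bHLH	4	2	3	3	6	5	8	13	3	4	0	4	4	4
bZIP	3	6	5	3	4	4	6	5	3	5	5	9	5	4
C2H2	0	3	4	4	5	6	5	9	6	11	5	3	3	6
C3H	3	2	7	3	3	0	2	2	3	2	0	5	1	5
CAMTA	0	0	0	0	0	0	2	2	2	5	0	0	2	0
CO-like	1	0	0	0	0	0	1	0	0	0	0	2	0	0
CPP	1	0	0	0	0	0	0	0	0	0	1	1	0	1
DBB	0	0	0	0	0	0	1	2	0	0	0	2	0	0
Dof	0	0	2	1	1	0	1	1	0	1	0	0	1	4
E2F/DP	0	0	1	0	0	0	0	2	0	1	0	1	0	0
EIL	0	0	0	0	1	0	0	0	1	0	0	0	0	0
ERF	0	3	3	1	3	3	7	1	1	3	2	1	0	10
FAR1	0	0	0	3	11	2	3	0	10	3	0	2	1	3
G2-like	1	2	1	2	4	0	3	2	1	4	3	1	1	2
GATA	2	1	0	1	2	1	1	2	2	0	0	1	0	2
GeBP	0	0	0	0	0	1	0	0	0	0	0	0	2	0
GRAS	0	0	3	1	4	11	6	0	1	0	2	0	1	4
GRF	0	0	0	0	0	0	0	1	0	1	0	0	0	0
HB-other	1	0	3	1	2	0	4	3	1	4	3	5	2	4
HD-ZIP	0	1	0	1	0	1	6	3	0	6	0	1	0	3
HSF	0	0	1	2	0	1	1	0	0	0	0	0	0	1
LBD	0	2	1	0	0	0	0	0	1	1	1	0	1	1
LSD	0	0	0	0	2	0	0	1	0	0	0	1	1	1
MIKC	0	0	0	2	1	2	3	2	0	4	0	1	1	2
M-type	0	1	3	1	3	1	2	4	2	3	7	3	2	0
MYB	1	1	0	0	1	2	1	2	0	4	0	4	1	11
MYB-related	4	1	6	2	4	2	10	7	6	6	5	8	2	2
NAC	0	6	7	7	6	7	11	14	5	15	11	12	17	10
NF-X1	1	1	0	0	1	1	1	2	1	1	1	1	1	2
NF-YA	0	0	1	0	1	0	1	1	1	0	0	0	0	0
NF-YB	0	0	1	0	0	0	0	3	0	1	2	0	0	1
NF-YC	0	1	1	1	1	0	0	0	1	0	1	0	0	0
Nin-like	1	2	0	1	1	0	0	2	1	1	0	0	1	2
RAV	0	0	0	0	0	0	0	0	0	0	0	2	0	0
S1Fa-like	1	2	2	1	2	1	2	4	3	4	1	2	3	2
SAP	0	0	0	0	0	0	0	0	1	1	0	0	0	0
SBP	9	4	2	4	5	5	7	9	3	9	3	8	5	4
SRS	0	0	0	0	0	0	0	1	2	1	0	1	1	1
TALE	0	0	0	0	0	1	0	0	0	0	1	0	0	1
TCP	0	0	2	0	0	0	3	0	0	0	0	1	0	5
Trihelix	0	2	2	0	0	0	3	3	0	4	2	1	0	5
Whirly	0	0	0	0	0	0	0	0	0	0	0	0	0	1
WOX	0	0	0	0	0	0	1	0	0	0	1	0	0	1
WRKY	0	1	5	0	6	3	3	4	5	1	1	0	0	2
YABBY	0	0	0	0	0	1	2	3	0	0	0	2	2	0
ZF-HD	0	0	0	0	2	0	0	1	2	0	0	0	0	3
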