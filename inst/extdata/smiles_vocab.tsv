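token	id
#	1
%	2
(	3
H	4
+	5
-	6
.	7
/	8
\	9
=	10
@	11
[	12
]	13
0	14
M	15
2	16
3	17
4	18
5	19
6	20
7	21
8	22
9	23
A	24
l	25
U	26
D	27
E	28
F	29
G	30
)	31
I	32
K	33
L	34
1	35
N	36
a	37
P	38
R	39
S	40
T	41
C	42
V	43
W	44
X	45
Y	46
Z	47
O	48
b	49
c	50
d	51
e	52
f	53
g	54
h	55
i	56
B	57
n	58
o	59
r	60
s	61
t	62
u	63
:	64
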