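aa	chi1	chi2	chi3	chi4	prob
S	-65	NA	NA	NA	0.48
S	180	NA	NA	NA	0.3
S	65	NA	NA	NA	0.22
C	-65	NA	NA	NA	0.55
C	180	NA	NA	NA	0.3
C	65	NA	NA	NA	0.15
T	60	NA	NA	NA	0.49
T	-60	NA	NA	NA	0.43
T	180	NA	NA	NA	0.08
V	175	NA	NA	NA	0.73
V	-60	NA	NA	NA	0.2
V	65	NA	NA	NA	0.07
I	-65	170	NA	NA	0.6
I	-65	-60	NA	NA	0.15
I	62	170	NA	NA	0.25
L	-65	175	NA	NA	0.62
L	180	65	NA	NA	0.29
L	-85	65	NA	NA	0.09
D	-70	-15	NA	NA	0.51
D	180	0	NA	NA	0.33
D	65	10	NA	NA	0.16
N	-65	-40	NA	NA	0.47
N	180	30	NA	NA	0.33
N	65	-20	NA	NA	0.2
E	-67	180	-10	NA	0.45
E	180	180	0	NA	0.35
E	65	180	10	NA	0.2
Q	-67	180	-25	NA	0.44
Q	180	65	0	NA	0.3
Q	65	180	20	NA	0.26
M	-65	180	75	NA	0.4
M	-65	180	-75	NA	0.3
M	180	180	75	NA	0.3
K	-67	180	180	180	0.5
K	180	180	180	180	0.35
K	65	180	180	180	0.15
R	-67	180	180	85	0.4
R	-67	180	180	180	0.3
R	180	180	65	85	0.3
H	-65	-70	NA	NA	0.5
H	180	80	NA	NA	0.3
H	65	-80	NA	NA	0.2
F	-65	90	NA	NA	0.52
F	180	80	NA	NA	0.33
F	65	90	NA	NA	0.15
Y	-65	90	NA	NA	0.53
Y	180	80	NA	NA	0.33
Y	65	90	NA	NA	0.14
W	-65	95	NA	NA	0.45
W	180	80	NA	NA	0.35
W	65	-90	NA	NA	0.2
P	25	-35	NA	NA	0.55
P	-25	35	NA	NA	0.45
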