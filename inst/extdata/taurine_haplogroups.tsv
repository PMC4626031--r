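name	parent	defining_variants	verified
root			yes
I	root	1633,5204,9386,13759	no
PQT	root	669,8306,12490	no
P	PQT	505,7443,15303	no
P1	P	1032,9682	no
QT	PQT	736,10310	no
Q	QT	15953G,3388,11217	partial
Q1	Q	1998,12792	no
Q1a	Q1	5312,14067	no
Q2	Q	4221,8868	no
T	QT	2129,6823,13310	no
T1'2'3	T	914,10601	no
T1	T1'2'3	3591,12906	no
T1a	T1	4892	no
T1b	T1	7197	no
T1b1	T1b	11425	no
T1c	T1	5817	no
T1c1	T1c	9402	no
T1c1a	T1c1	13866	no
T1d	T1	6336	no
T1d1	T1d	10988	no
T1e	T1	8741	no
T1f	T1	12018	no
T2	T1'2'3	3446,9718	no
T3	T1'2'3	1287,14477	no
T3a	T3	5501	no
T4	T3a	8316	no
T3b	T3	7034	no
T5	T	2781,11902	no
T5a	T5	6145	no
T5b	T5	9963	no
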