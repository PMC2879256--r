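# version: 1.0
# FFM-FM polynomial coefficient registry: FFM (kg) as a function of
# F = fat mass (kg), A = age (y), H = height (cm), per (race, sex) group.
# Variants: printed = literal transcription of the published table;
# normalized = the two typographically anomalous terms replaced by their
# pattern-consistent F*A and F^3*H forms; corrected = normalized with the
# AA-female row repaired (H coefficient 0.7; intercept and F coefficient
# recalibrated to interpolate the published reference compositions
# FFM(27.75)=47.25 and FFM(20.74)=44.26 kg at A=34 y, H=165 cm).
variant	race	sex	term	value
normalized	AA	F	1	-69
normalized	AA	F	F	2.5
normalized	AA	F	A	-0.040000000000000001
normalized	AA	F	H	0.29999999999999999
normalized	AA	F	FA	-0.002
normalized	AA	F	FH	-0.01
normalized	AA	F	F2	-0.047
normalized	AA	F	F2A	3.0000000000000001e-05
normalized	AA	F	F3	0.00020000000000000001
normalized	AA	F	F4	3.9999999999999998e-07
normalized	AA	F	F2H	0.00029999999999999997
normalized	AA	F	F3H	-1.9999999999999999e-06
normalized	AA	M	1	-69
normalized	AA	M	F	3.6000000000000001
normalized	AA	M	A	-0.040000000000000001
normalized	AA	M	H	0.69999999999999996
normalized	AA	M	FA	-0.002
normalized	AA	M	FH	-0.01
normalized	AA	M	F2	-0.070000000000000007
normalized	AA	M	F2A	3.0000000000000001e-05
normalized	AA	M	F3	0.00069999999999999999
normalized	AA	M	F4	-1.9999999999999999e-06
normalized	AA	M	F2H	0.00029999999999999997
normalized	AA	M	F3H	-1.9999999999999999e-06
normalized	NAA	F	1	-72.099999999999994
normalized	NAA	F	F	2.5
normalized	NAA	F	A	-0.040000000000000001
normalized	NAA	F	H	0.69999999999999996
normalized	NAA	F	FA	-0.002
normalized	NAA	F	FH	-0.01
normalized	NAA	F	F2	-0.040000000000000001
normalized	NAA	F	F2A	3.0000000000000001e-05
normalized	NAA	F	F3	0.00020000000000000001
normalized	NAA	F	F4	3.9999999999999998e-07
normalized	NAA	F	F2H	0.00029999999999999997
normalized	NAA	F	F3H	-1.9999999999999999e-06
normalized	NAA	M	1	-71.700000000000003
normalized	NAA	M	F	3.6000000000000001
normalized	NAA	M	A	-0.040000000000000001
normalized	NAA	M	H	0.69999999999999996
normalized	NAA	M	FA	-0.002
normalized	NAA	M	FH	-0.01
normalized	NAA	M	F2	-0.070000000000000007
normalized	NAA	M	F2A	3.0000000000000001e-05
normalized	NAA	M	F3	0.00059999999999999995
normalized	NAA	M	F4	-1.9999999999999999e-06
normalized	NAA	M	F2H	0.00029999999999999997
normalized	NAA	M	F3H	-1.9999999999999999e-06
printed	AA	F	1	-69
printed	AA	F	F	2.5
printed	AA	F	A	-0.040000000000000001
printed	AA	F	H	0.29999999999999999
printed	AA	F	FA	-0.002
printed	AA	F	FH	-0.01
printed	AA	F	F2	-0.047
printed	AA	F	F2A	3.0000000000000001e-05
printed	AA	F	F3	0.00020000000000000001
printed	AA	F	F4	3.9999999999999998e-07
printed	AA	F	F2H	0.00029999999999999997
printed	AA	F	F3H	-1.9999999999999999e-06
printed	AA	M	1	-69
printed	AA	M	F	3.6000000000000001
printed	AA	M	A	-0.040000000000000001
printed	AA	M	H	0.69999999999999996
printed	AA	M	FA	-0.002
printed	AA	M	FH	-0.010002
printed	AA	M	F2	-0.070000000000000007
printed	AA	M	F2A	3.0000000000000001e-05
printed	AA	M	F3	0.00069999999999999999
printed	AA	M	F4	-1.9999999999999999e-06
printed	AA	M	F2H	0.00029999999999999997
printed	AA	M	F3H	0
printed	NAA	F	1	-72.099999999999994
printed	NAA	F	F	2.5
printed	NAA	F	A	-0.042000000000000003
printed	NAA	F	H	0.69999999999999996
printed	NAA	F	FA	0
printed	NAA	F	FH	-0.01
printed	NAA	F	F2	-0.040000000000000001
printed	NAA	F	F2A	3.0000000000000001e-05
printed	NAA	F	F3	0.00020000000000000001
printed	NAA	F	F4	3.9999999999999998e-07
printed	NAA	F	F2H	0.00029999999999999997
printed	NAA	F	F3H	-1.9999999999999999e-06
printed	NAA	M	1	-71.700000000000003
printed	NAA	M	F	3.6000000000000001
printed	NAA	M	A	-0.040000000000000001
printed	NAA	M	H	0.69999999999999996
printed	NAA	M	FA	-0.002
printed	NAA	M	FH	-0.01
printed	NAA	M	F2	-0.070000000000000007
printed	NAA	M	F2A	3.0000000000000001e-05
printed	NAA	M	F3	0.00059999999999999995
printed	NAA	M	F4	-1.9999999999999999e-06
printed	NAA	M	F2H	0.00029999999999999997
printed	NAA	M	F3H	-1.9999999999999999e-06
corrected	AA	F	1	-79.919620675222632
corrected	AA	F	F	2.1814163114382032
corrected	AA	F	A	-0.040000000000000001
corrected	AA	F	H	0.69999999999999996
corrected	AA	F	FA	-0.002
corrected	AA	F	FH	-0.01
corrected	AA	F	F2	-0.047
corrected	AA	F	F2A	3.0000000000000001e-05
corrected	AA	F	F3	0.00020000000000000001
corrected	AA	F	F4	3.9999999999999998e-07
corrected	AA	F	F2H	0.00029999999999999997
corrected	AA	F	F3H	-1.9999999999999999e-06
corrected	AA	M	1	-69
corrected	AA	M	F	3.6000000000000001
corrected	AA	M	A	-0.040000000000000001
corrected	AA	M	H	0.69999999999999996
corrected	AA	M	FA	-0.002
corrected	AA	M	FH	-0.01
corrected	AA	M	F2	-0.070000000000000007
corrected	AA	M	F2A	3.0000000000000001e-05
corrected	AA	M	F3	0.00069999999999999999
corrected	AA	M	F4	-1.9999999999999999e-06
corrected	AA	M	F2H	0.00029999999999999997
corrected	AA	M	F3H	-1.9999999999999999e-06
corrected	NAA	F	1	-72.099999999999994
corrected	NAA	F	F	2.5
corrected	NAA	F	A	-0.040000000000000001
corrected	NAA	F	H	0.69999999999999996
corrected	NAA	F	FA	-0.002
corrected	NAA	F	FH	-0.01
corrected	NAA	F	F2	-0.040000000000000001
corrected	NAA	F	F2A	3.0000000000000001e-05
corrected	NAA	F	F3	0.00020000000000000001
corrected	NAA	F	F4	3.9999999999999998e-07
corrected	NAA	F	F2H	0.00029999999999999997
corrected	NAA	F	F3H	-1.9999999999999999e-06
corrected	NAA	M	1	-71.700000000000003
corrected	NAA	M	F	3.6000000000000001
corrected	NAA	M	A	-0.040000000000000001
corrected	NAA	M	H	0.69999999999999996
corrected	NAA	M	FA	-0.002
corrected	NAA	M	FH	-0.01
corrected	NAA	M	F2	-0.070000000000000007
corrected	NAA	M	F2A	3.0000000000000001e-05
corrected	NAA	M	F3	0.00059999999999999995
corrected	NAA	M	F4	-1.9999999999999999e-06
corrected	NAA	M	F2H	0.00029999999999999997
corrected	NAA	M	F3H	-1.9999999999999999e-06
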