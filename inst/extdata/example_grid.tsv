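# Example 96-cell 2DE gel calibration.
# Self-consistent reconstruction anchored on published cell bounds:
#   E5  = pI 6.30-6.88 x MW 40-52 kDa
#   C8  = pI 5.11-5.80
#   H2  = pI 8.90-10.00
#   H12 = MW 6-15 kDa
# The published bounds, taken together, do not define a single monotone
# column/row layout; this reconstruction keeps the anchored cells and fills
# the remaining bands monotonically (pI decreasing with column number,
# MW decreasing from row A to row H). Intervals are half-open, lower-inclusive.
row_letter	col_number	pi_lo	pi_hi	mw_lo_kda	mw_hi_kda
A	1	10.00	11.00	116	250
A	2	8.90	10.00	116	250
A	3	8.00	8.90	116	250
A	4	6.88	8.00	116	250
A	5	6.30	6.88	116	250
A	6	6.05	6.30	116	250
A	7	5.80	6.05	116	250
A	8	5.11	5.80	116	250
A	9	4.70	5.11	116	250
A	10	4.30	4.70	116	250
A	11	3.80	4.30	116	250
A	12	3.00	3.80	116	250
B	1	10.00	11.00	87	116
B	2	8.90	10.00	87	116
B	3	8.00	8.90	87	116
B	4	6.88	8.00	87	116
B	5	6.30	6.88	87	116
B	6	6.05	6.30	87	116
B	7	5.80	6.05	87	116
B	8	5.11	5.80	87	116
B	9	4.70	5.11	87	116
B	10	4.30	4.70	87	116
B	11	3.80	4.30	87	116
B	12	3.00	3.80	87	116
C	1	10.00	11.00	66	87
C	2	8.90	10.00	66	87
C	3	8.00	8.90	66	87
C	4	6.88	8.00	66	87
C	5	6.30	6.88	66	87
C	6	6.05	6.30	66	87
C	7	5.80	6.05	66	87
C	8	5.11	5.80	66	87
C	9	4.70	5.11	66	87
C	10	4.30	4.70	66	87
C	11	3.80	4.30	66	87
C	12	3.00	3.80	66	87
D	1	10.00	11.00	52	66
D	2	8.90	10.00	52	66
D	3	8.00	8.90	52	66
D	4	6.88	8.00	52	66
D	5	6.30	6.88	52	66
D	6	6.05	6.30	52	66
D	7	5.80	6.05	52	66
D	8	5.11	5.80	52	66
D	9	4.70	5.11	52	66
D	10	4.30	4.70	52	66
D	11	3.80	4.30	52	66
D	12	3.00	3.80	52	66
E	1	10.00	11.00	40	52
E	2	8.90	10.00	40	52
E	3	8.00	8.90	40	52
E	4	6.88	8.00	40	52
E	5	6.30	6.88	40	52
E	6	6.05	6.30	40	52
E	7	5.80	6.05	40	52
E	8	5.11	5.80	40	52
E	9	4.70	5.11	40	52
E	10	4.30	4.70	40	52
E	11	3.80	4.30	40	52
E	12	3.00	3.80	40	52
F	1	10.00	11.00	30	40
F	2	8.90	10.00	30	40
F	3	8.00	8.90	30	40
F	4	6.88	8.00	30	40
F	5	6.30	6.88	30	40
F	6	6.05	6.30	30	40
F	7	5.80	6.05	30	40
F	8	5.11	5.80	30	40
F	9	4.70	5.11	30	40
F	10	4.30	4.70	30	40
F	11	3.80	4.30	30	40
F	12	3.00	3.80	30	40
G	1	10.00	11.00	15	30
G	2	8.90	10.00	15	30
G	3	8.00	8.90	15	30
G	4	6.88	8.00	15	30
G	5	6.30	6.88	15	30
G	6	6.05	6.30	15	30
G	7	5.80	6.05	15	30
G	8	5.11	5.80	15	30
G	9	4.70	5.11	15	30
G	10	4.30	4.70	15	30
G	11	3.80	4.30	15	30
G	12	3.00	3.80	15	30
H	1	10.00	11.00	6	15
H	2	8.90	10.00	6	15
H	3	8.00	8.90	6	15
H	4	6.88	8.00	6	15
H	5	6.30	6.88	6	15
H	6	6.05	6.30	6	15
H	7	5.80	6.05	6	15
H	8	5.11	5.80	6	15
H	9	4.70	5.11	6	15
H	10	4.30	4.70	6	15
H	11	3.80	4.30	6	15
H	12	3.00	3.80	6	15
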