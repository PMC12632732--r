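label	theta_deg	azimuth_deg
Fp1	72	-18
AF7	72	-36
AF3	61.828159725424	-19.5020263846303
F1	42.2633437591278	-19.3482564966081
F3	51.0069818569306	-33.8587372057305
F5	61.1327600600232	-44.9527460758476
F7	72	-54
FT7	72	-72
FC5	56.1517034917186	-65.6220747615537
FC3	40.7834337331844	-56.3141446051617
FC1	26.8229863288272	-38.9952925222474
C1	18	-90
C3	36	-90
C5	54	-90
T7	72	-90
TP7	72	-108
CP5	56.1517034917186	-114.377925238446
CP3	40.7834337331844	-123.685855394838
CP1	26.8229863288272	-141.004707477753
P1	42.2633437591278	-160.651743503392
P3	51.0069818569306	-146.141262794269
P5	61.1327600600232	-135.047253924152
P7	72	-126
P9	90	-126
PO7	72	-144
PO3	61.828159725424	-160.49797361537
O1	72	-162
Iz	90	180
Oz	72	180
POz	54	180
Pz	36	180
CPz	18	180
Fpz	72	0
Fp2	72	18
AF8	72	36
AF4	61.828159725424	19.5020263846303
AFz	54	0
Fz	36	0
F2	42.2633437591278	19.3482564966081
F4	51.0069818569306	33.8587372057305
F6	61.1327600600232	44.9527460758476
F8	72	54
FT8	72	72
FC6	56.1517034917186	65.6220747615537
FC4	40.7834337331844	56.3141446051617
FC2	26.8229863288272	38.9952925222474
FCz	18	0
Cz	0	0
C2	18	90
C4	36	90
C6	54	90
T8	72	90
TP8	72	108
CP6	56.1517034917186	114.377925238446
CP4	40.7834337331844	123.685855394838
CP2	26.8229863288272	141.004707477753
P2	42.2633437591278	160.651743503392
P4	51.0069818569306	146.141262794269
P6	61.1327600600232	135.047253924152
P8	72	126
P10	90	126
PO8	72	144
PO4	61.828159725424	160.49797361537
O2	72	162
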