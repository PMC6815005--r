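D001,T_ROOT,T_C1_L1_1
D001,T_C1_L1_1,T_C1_L2_1
D001,T_C1_L2_1,T_C1_L3_1
D001,T_C1_L3_1,D001
D002,T_ROOT,T_C2_L1_1
D002,T_C2_L1_1,T_C2_L2_1
D002,T_C2_L2_1,T_C2_L3_1
D002,T_C2_L3_1,D002
D003,T_ROOT,T_C3_L1_1
D003,T_C3_L1_1,T_C3_L2_1
D003,T_C3_L2_1,T_C3_L3_1
D003,T_C3_L3_1,D003
D004,T_ROOT,T_C1_L1_1
D004,T_C1_L1_1,T_C1_L2_1
D004,T_C1_L2_1,T_C1_L3_1
D004,T_C1_L3_1,D004
D005,T_ROOT,T_C2_L1_1
D005,T_C2_L1_1,T_C2_L2_1
D005,T_C2_L2_1,T_C2_L3_1
D005,T_C2_L3_1,D005
D006,T_ROOT,T_C3_L1_1
D006,T_C3_L1_1,T_C3_L2_1
D006,T_C3_L2_1,T_C3_L3_1
D006,T_C3_L3_1,D006
D007,T_ROOT,T_C1_L1_1
D007,T_C1_L1_1,T_C1_L2_1
D007,T_C1_L2_1,T_C1_L3_1
D007,T_C1_L3_1,D007
D008,T_ROOT,T_C2_L1_1
D008,T_C2_L1_1,T_C2_L2_1
D008,T_C2_L2_1,T_C2_L3_1
D008,T_C2_L3_1,D008
D009,T_ROOT,T_C3_L1_1
D009,T_C3_L1_1,T_C3_L2_1
D009,T_C3_L2_1,T_C3_L3_1
D009,T_C3_L3_1,D009
D010,T_ROOT,T_C1_L1_1
D010,T_C1_L1_1,T_C1_L2_1
D010,T_C1_L2_1,T_C1_L3_1
D010,T_C1_L3_1,D010
D011,T_ROOT,T_C2_L1_1
D011,T_C2_L1_1,T_C2_L2_1
D011,T_C2_L2_1,T_C2_L3_1
D011,T_C2_L3_1,D011
D012,T_ROOT,T_C3_L1_1
D012,T_C3_L1_1,T_C3_L2_1
D012,T_C3_L2_1,T_C3_L3_1
D012,T_C3_L3_1,D012
D013,T_ROOT,T_C1_L1_1
D013,T_C1_L1_1,T_C1_L2_1
D013,T_C1_L2_1,T_C1_L3_1
D013,T_C1_L3_1,D013
D014,T_ROOT,T_C2_L1_1
D014,T_C2_L1_1,T_C2_L2_1
D014,T_C2_L2_1,T_C2_L3_1
D014,T_C2_L3_1,D014
D015,T_ROOT,T_C3_L1_1
D015,T_C3_L1_1,T_C3_L2_1
D015,T_C3_L2_1,T_C3_L3_1
D015,T_C3_L3_1,D015
D016,T_ROOT,T_C1_L1_1
D016,T_C1_L1_1,T_C1_L2_1
D016,T_C1_L2_1,T_C1_L3_1
D016,T_C1_L3_1,D016
D017,T_ROOT,T_C2_L1_1
D017,T_C2_L1_1,T_C2_L2_1
D017,T_C2_L2_1,T_C2_L3_1
D017,T_C2_L3_1,D017
D018,T_ROOT,T_C3_L1_1
D018,T_C3_L1_1,T_C3_L2_1
D018,T_C3_L2_1,T_C3_L3_1
D018,T_C3_L3_1,D018
D019,T_ROOT,T_C1_L1_1
D019,T_C1_L1_1,T_C1_L2_1
D019,T_C1_L2_1,T_C1_L3_1
D019,T_C1_L3_1,D019
D020,T_ROOT,T_C2_L1_1
D020,T_C2_L1_1,T_C2_L2_1
D020,T_C2_L2_1,T_C2_L3_1
D020,T_C2_L3_1,D020
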