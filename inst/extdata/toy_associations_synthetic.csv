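D001,M022
D001,M025
D001,M035
D001,M037
D001,M043
D001,M055
D001,M058
D002,M011
D002,M017
D002,M020
D002,M029
D002,M032
D002,M050
D002,M057
D003,M009
D003,M018
D003,M021
D003,M027
D003,M030
D003,M038
D003,M039
D004,M004
D004,M010
D004,M013
D004,M016
D004,M025
D004,M034
D004,M049
D004,M052
D004,M054
D005,M008
D005,M015
D005,M017
D005,M026
D005,M048
D005,M050
D005,M056
D005,M059
D006,M003
D006,M015
D006,M024
D006,M032
D006,M033
D006,M042
D006,M045
D006,M054
D007,M010
D007,M019
D007,M034
D007,M040
D007,M041
D007,M046
D007,M049
D007,M055
D008,M014
D008,M016
D008,M044
D008,M052
D008,M059
D009,M009
D009,M021
D009,M030
D009,M033
D009,M057
D009,M060
D010,M004
D010,M016
D010,M022
D010,M025
D010,M028
D010,M034
D010,M037
D010,M038
D011,M002
D011,M008
D011,M017
D011,M023
D011,M032
D012,M015
D012,M018
D012,M027
D012,M048
D013,M001
D013,M031
D013,M034
D013,M043
D013,M044
D013,M052
D013,M056
D014,M014
D014,M020
D014,M023
D014,M026
D014,M029
D014,M038
D014,M039
D014,M041
D014,M044
D014,M047
D014,M048
D014,M050
D014,M053
D014,M060
D015,M003
D015,M006
D015,M024
D015,M027
D015,M033
D015,M048
D015,M051
D016,M001
D016,M004
D016,M010
D016,M019
D016,M037
D016,M043
D016,M047
D017,M003
D017,M005
D017,M008
D017,M017
D017,M020
D017,M026
D017,M029
D017,M032
D017,M035
D017,M038
D017,M040
D017,M046
D017,M053
D018,M012
D018,M030
D018,M033
D018,M039
D018,M048
D018,M060
D019,M006
D019,M010
D019,M049
D019,M051
D019,M054
D019,M058
D020,M005
D020,M007
D020,M012
D020,M020
D020,M026
D020,M035
D020,M036
D020,M044
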