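cohort	mouse_id
SB-Onc2.3	SBOnc2.3_M001
SB-Onc2.3	SBOnc2.3_M002
SB-Onc2.3	SBOnc2.3_M003
SB-Onc2.3	SBOnc2.3_M004
SB-Onc2.3	SBOnc2.3_M005
SB-Onc2.3	SBOnc2.3_M006
SB-Onc2.3	SBOnc2.3_M007
SB-Onc2.3	SBOnc2.3_M008
SB-Onc2.3	SBOnc2.3_M009
SB-Onc2.3	SBOnc2.3_M010
SB-Onc2.3	SBOnc2.3_M011
SB-Onc2.3	SBOnc2.3_M012
SB-Onc2.3	SBOnc2.3_M013
SB-Onc2.3	SBOnc2.3_M014
SB-Onc2.3	SBOnc2.3_M015
SB-Onc2.3	SBOnc2.3_M016
SB-Onc2.3	SBOnc2.3_M017
SB-Onc2.3	SBOnc2.3_M018
SB-Onc2.3	SBOnc2.3_M019
SB-Onc2.3	SBOnc2.3_M020
SB-Onc2.3	SBOnc2.3_M021
SB-Onc2.3	SBOnc2.3_M022
SB-Onc2.3	SBOnc2.3_M023
SB-Onc2.3	SBOnc2.3_M024
SB-Onc2.3	SBOnc2.3_M025
SB-Onc2.3	SBOnc2.3_M026
SB-Onc2.3	SBOnc2.3_M027
SB-Onc2.3	SBOnc2.3_M028
SB-Onc2.3	SBOnc2.3_M029
SB-Onc2.3	SBOnc2.3_M030
SB-Onc2.3	SBOnc2.3_M031
SB-Onc2.3	SBOnc2.3_M032
SB-Onc2.3	SBOnc2.3_M033
SB-Onc2.3	SBOnc2.3_M034
SB-Onc2.3	SBOnc2.3_M035
SB-Onc2.3	SBOnc2.3_M036
SB-Onc2.3	SBOnc2.3_M037
SB-Onc2.3	SBOnc2.3_M038
SB-Onc2.3	SBOnc2.3_M039
SB-Onc2.3	SBOnc2.3_M040
SB-Onc2.3	SBOnc2.3_M041
SB-Onc2.3	SBOnc2.3_M042
SB-Onc2.3	SBOnc2.3_M043
SB-Onc2.3	SBOnc2.3_M044
SB-Onc2.3	SBOnc2.3_M045
SB-Onc2.3	SBOnc2.3_M046
SB-Onc2.3	SBOnc2.3_M047
SB-Onc2.3	SBOnc2.3_M048
SB-Onc2.3	SBOnc2.3_M049
SB-Onc2.3	SBOnc2.3_M050
SB-Onc2.3	SBOnc2.3_M051
SB-Onc2.3	SBOnc2.3_M052
SB-Onc2.3	SBOnc2.3_M053
SB-Onc2.3	SBOnc2.3_M054
SB-Onc2.3	SBOnc2.3_M055
SB-Onc2.3	SBOnc2.3_M056
SB-Onc2.3	SBOnc2.3_M057
SB-Onc2.3	SBOnc2.3_M058
SB-Onc2.3	SBOnc2.3_M059
SB-Onc2.3	SBOnc2.3_M060
SB-Onc2.3	SBOnc2.3_M061
SB-Onc2.3	SBOnc2.3_M062
SB-Onc2.3	SBOnc2.3_M063
SB-Onc2.3	SBOnc2.3_M064
SB-Onc2.3	SBOnc2.3_M065
SB-Onc2.3	SBOnc2.3_M066
SB-Onc2.3	SBOnc2.3_M067
SB-Onc2.3	SBOnc2.3_M068
SB-Onc2.3	SBOnc2.3_M069
SB-Onc2.3	SBOnc2.3_M070
SB-Onc2.3	SBOnc2.3_M071
SB-Onc2.3	SBOnc2.3_M072
SB-Onc2.3	SBOnc2.3_M073
SB-Onc2.3	SBOnc2.3_M074
SB-Onc2.3	SBOnc2.3_M075
SB-Onc2.3	SBOnc2.3_M076
SB-Onc2.3	SBOnc2.3_M077
SB-Onc2.3	SBOnc2.3_M078
SB-Onc2.3	SBOnc2.3_M079
SB-Onc2.3	SBOnc2.3_M080
SB-Onc2.3	SBOnc2.3_M081
SB-Onc2.3	SBOnc2.3_M082
SB-Onc2.3	SBOnc2.3_M083
SB-Onc2.3	SBOnc2.3_M084
SB-Onc2.3	SBOnc2.3_M085
SB-Onc2.3	SBOnc2.3_M086
SB-Onc2.3	SBOnc2.3_M087
SB-Onc2.3	SBOnc2.3_M088
SB-Onc2.3	SBOnc2.3_M089
SB-Onc2.3	SBOnc2.3_M090
SB-Onc2.3	SBOnc2.3_M091
SB-Onc2.3	SBOnc2.3_M092
SB-Onc2.3	SBOnc2.3_M093
SB-Onc2.3	SBOnc2.3_M094
SB-Onc2.3	SBOnc2.3_M095
SB-Onc2.3	SBOnc2.3_M096
SB-Onc2.3	SBOnc2.3_M097
SB-Onc2.3	SBOnc2.3_M098
SB-Onc2.3	SBOnc2.3_M099
SB-Onc2.3	SBOnc2.3_M100
SB-Onc2.3	SBOnc2.3_M101
SB-Onc2.3	SBOnc2.3_M102
SB-Onc2.3	SBOnc2.3_M103
SB-Onc2.3	SBOnc2.3_M104
SB-Onc2.3	SBOnc2.3_M105
SB-Onc2.3	SBOnc2.3_M106
SB-Onc2.3	SBOnc2.3_M107
SB-Onc3	SBOnc3_M001
SB-Onc3	SBOnc3_M002
SB-Onc3	SBOnc3_M003
SB-Onc3	SBOnc3_M004
SB-Onc3	SBOnc3_M005
SB-Onc3	SBOnc3_M006
SB-Onc3	SBOnc3_M007
SB-Onc3	SBOnc3_M008
SB-Onc3	SBOnc3_M009
SB-Onc3	SBOnc3_M010
SB-Onc3	SBOnc3_M011
SB-Onc3	SBOnc3_M012
SB-Onc3	SBOnc3_M013
SB-Onc3	SBOnc3_M014
SB-Onc3	SBOnc3_M015
SB-Onc3	SBOnc3_M016
SB-Onc3	SBOnc3_M017
SB-Onc3	SBOnc3_M018
SB-Onc3	SBOnc3_M019
SB-Onc3	SBOnc3_M020
SB-Onc3	SBOnc3_M021
SB-Onc3	SBOnc3_M022
SB-Onc3	SBOnc3_M023
SB-Onc3	SBOnc3_M024
SB-Onc3	SBOnc3_M025
SB-Onc3	SBOnc3_M026
SB-Onc3	SBOnc3_M027
SB-Onc3	SBOnc3_M028
SB-Onc3	SBOnc3_M029
SB-Onc3	SBOnc3_M030
SB-Onc3	SBOnc3_M031
SB-Onc3	SBOnc3_M032
SB-Onc3	SBOnc3_M033
SB-Onc3	SBOnc3_M034
SB-Onc3	SBOnc3_M035
SB-Onc3	SBOnc3_M036
SB-Onc3	SBOnc3_M037
SB-Onc3	SBOnc3_M038
SB-Onc3	SBOnc3_M039
SB-Onc3	SBOnc3_M040
SB-Onc3	SBOnc3_M041
SB-Onc3	SBOnc3_M042
SB-Onc3	SBOnc3_M043
SB-Onc3	SBOnc3_M044
SB-Onc3	SBOnc3_M045
SB-Onc3	SBOnc3_M046
SB-Onc3	SBOnc3_M047
SB-Onc3	SBOnc3_M048
SB-Onc3	SBOnc3_M049
SB-Onc3	SBOnc3_M050
SB-Onc3	SBOnc3_M051
SB-Onc3	SBOnc3_M052
SB-Onc3	SBOnc3_M053
SB-Onc3	SBOnc3_M054
SB-Onc3	SBOnc3_M055
SB-Onc3	SBOnc3_M056
SB-Onc3	SBOnc3_M057
SB-Onc3	SBOnc3_M058
SB-Onc3	SBOnc3_M059
SB-Onc3	SBOnc3_M060
SB-Onc3	SBOnc3_M061
SB-Onc3	SBOnc3_M062
SB-Onc3	SBOnc3_M063
SB-Onc3	SBOnc3_M064
SB-Onc3	SBOnc3_M065
SB-Onc3	SBOnc3_M066
SB-Onc3	SBOnc3_M067
SB-Onc3	SBOnc3_M068
SB-Onc3	SBOnc3_M069
SB-Onc3	SBOnc3_M070
SB-Onc3	SBOnc3_M071
SB-Onc3	SBOnc3_M072
SB-Onc3	SBOnc3_M073
SB-Onc3	SBOnc3_M074
SB-Onc3	SBOnc3_M075
SB-Onc3	SBOnc3_M076
SB-Onc3	SBOnc3_M077
SB-Onc3	SBOnc3_M078
SB-Onc3	SBOnc3_M079
SB-Onc3	SBOnc3_M080
SB-Onc3	SBOnc3_M081
SB-Onc3	SBOnc3_M082
SB-Onc3	SBOnc3_M083
SB-Onc3	SBOnc3_M084
SB-Onc3	SBOnc3_M085
SB-Onc3	SBOnc3_M086
SB-Onc3	SBOnc3_M087
SB-Onc2	SBOnc2_M001
SB-Onc2	SBOnc2_M002
SB-Onc2	SBOnc2_M003
SB-Onc2	SBOnc2_M004
SB-Onc2	SBOnc2_M005
SB-Onc2	SBOnc2_M006
SB-Onc2	SBOnc2_M007
SB-Onc2	SBOnc2_M008
SB-Onc2	SBOnc2_M009
SB-Onc2	SBOnc2_M010
SB-Onc2	SBOnc2_M011
SB-Onc2	SBOnc2_M012
SB-Onc2	SBOnc2_M013
SB-Onc2	SBOnc2_M014
SB-Onc2	SBOnc2_M015
SB-Onc2	SBOnc2_M016
SB-Onc2	SBOnc2_M017
SB-Onc2	SBOnc2_M018
SB-Onc2	SBOnc2_M019
SB-Onc2	SBOnc2_M020
SB-Onc2	SBOnc2_M021
SB-Onc2	SBOnc2_M022
SB-Onc2	SBOnc2_M023
SB-Onc2	SBOnc2_M024
SB-Onc2	SBOnc2_M025
SB-Onc2	SBOnc2_M026
SB-Onc2	SBOnc2_M027
SB-Onc2	SBOnc2_M028
SB-Onc2	SBOnc2_M029
SB-Onc2	SBOnc2_M030
SB-Onc2	SBOnc2_M031
SB-Onc2	SBOnc2_M032
SB-Onc2	SBOnc2_M033
SB-Onc2	SBOnc2_M034
SB-Onc2	SBOnc2_M035
SB-Onc2	SBOnc2_M036
SB-Onc2	SBOnc2_M037
SB-Onc2	SBOnc2_M038
SB-Onc2	SBOnc2_M039
SB-Onc2	SBOnc2_M040
SB-Onc2	SBOnc2_M041
SB-Onc2	SBOnc2_M042
SB-Onc2	SBOnc2_M043
SB-Onc2	SBOnc2_M044
SB-Onc2	SBOnc2_M045
SB-Onc2	SBOnc2_M046
SB-Onc2	SBOnc2_M047
SB-Onc2	SBOnc2_M048
SB-Onc2	SBOnc2_M049
SB-Onc2	SBOnc2_M050
SB-Onc2	SBOnc2_M051
SB-Onc2	SBOnc2_M052
SB-Onc2	SBOnc2_M053
SB-Onc2	SBOnc2_M054
SB-Onc2	SBOnc2_M055
SB-Onc2	SBOnc2_M056
SB-Onc2	SBOnc2_M057
SB-Onc2	SBOnc2_M058
SB-Onc2	SBOnc2_M059
SB-Onc2	SBOnc2_M060
SB-Onc2	SBOnc2_M061
SB-Onc2	SBOnc2_M062
SB-Onc2	SBOnc2_M063
SB-Onc2	SBOnc2_M064
SB-Onc2	SBOnc2_M065
SB-Onc2	SBOnc2_M066
SB-Onc2	SBOnc2_M067
SB-Onc2	SBOnc2_M068
SB-Onc2	SBOnc2_M069
SB-Onc2	SBOnc2_M070
SB-Onc2	SBOnc2_M071
SB-Onc2	SBOnc2_M072
SB-Onc2	SBOnc2_M073
SB-Onc2	SBOnc2_M074
SB-Onc2	SBOnc2_M075
SB-Onc2	SBOnc2_M076
SB-Onc2	SBOnc2_M077
SB-Onc2	SBOnc2_M078
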