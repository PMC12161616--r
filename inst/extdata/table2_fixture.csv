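participant_id,exercise_base,exercise_int,exercise_change_printed,breaks_base,breaks_int,breaks_change_printed,distance_base,distance_int,distance_change_printed,eses_base,eses_int,eses_change_printed
02,2.8,4.4,57,14.8,13.5,-9,0.4,0.4,0,37.0,37.0,0
03,27.9,37.0,33,15.4,19.1,24,0.6,0.6,0,32.0,35.0,9
04,26.8,99.0,269,9.4,12.3,31,0.1,0.2,100,40.0,39.0,-3
05,42.9,73.3,71,19.4,20.1,4,0.7,1.3,86,34.0,38.0,12
07,47.0,17.1,-64,24.0,13.8,-43,1.7,0.8,-53,34.0,34.0,0
08,23.9,27.8,16,17.2,17.8,3,0.5,0.6,20,31.0,30.0,-3
10,57.8,44.1,-24,17.6,18.1,3,1.0,1.0,0,40.0,39.0,-3
11,45.0,48.5,8,22.0,21.7,-1,1.4,0.8,-43,37.0,40.0,8
14,11.8,11.1,-6,14.1,11.8,-16,1.0,0.7,-30,27.0,34.0,26
15,18.6,21.5,16,18.2,17.7,-3,2.1,1.8,-14,27.0,36.0,33
16,1.1,9.9,800,13.2,11.9,-10,0.2,0.4,100,33.0,34.0,3
17,32.9,39.6,20,20.4,20.9,2,0.6,0.8,33,30.0,37.0,23
19,5.9,18.1,207,13.0,17.9,38,0.4,0.8,100,38.0,37.0,-3
21,27.0,29.0,7,19.4,16.1,-17,0.8,0.7,-13,39.0,39.0,0
25,12.9,13.5,5,15.1,13.9,-8,0.1,0.3,200,36.0,29.0,-19
26,38.8,39.3,1,17.6,16.5,-6,1.1,0.8,-27,28.0,37.0,32
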