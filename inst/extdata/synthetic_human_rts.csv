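"image_id","cue_id","model_rt","human_rt"
1,1,5,1081.2
1,2,5,348.2
1,3,5,453.9
2,1,6,553.3
2,2,6,435.8
2,3,6,440.7
3,1,7,837.4
3,2,7,655.4
3,3,7,712.1
4,1,8,1180.8
4,2,8,795.1
4,3,8,1291.6
5,1,9,1240
5,2,9,828.2
5,3,9,1158.9
6,1,10,898.4
6,2,10,612
6,3,10,735.3
7,1,11,839
7,2,11,1047.9
7,3,11,1016.7
8,1,12,1028.4
8,2,12,1154.8
8,3,12,588
9,1,13,1187.8
9,2,13,958.8
9,3,13,1078.3
10,1,14,1084.5
10,2,14,753.2
10,3,14,901.9
11,1,15,816.8
11,2,15,1151.2
11,3,15,1023.3
12,1,16,1023.5
12,2,16,951.5
12,3,16,921.7
13,1,17,1289.9
13,2,17,847.5
13,3,17,1050.1
14,1,18,1186.3
14,2,18,1376.4
14,3,18,972.9
15,1,19,1099.9
15,2,19,884.1
15,3,19,1077.7
16,1,20,1115.5
16,2,20,1484.1
16,3,20,1324.4
17,1,21,1261.1
17,2,21,1435.9
17,3,21,1184.7
18,1,22,1278.4
18,2,22,1357.2
18,3,22,1639.2
19,1,23,1472.3
19,2,23,1421.2
19,3,23,990.1
20,1,24,1427
20,2,24,1394.9
20,3,24,1170.7
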