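patient,n_lesions,lesion_volumes_cc,total_volume_cc,rmax_x_cm,rmax_y_cm,rmax_z_cm
1,2,10;9.3,19.3,7.8,8.8,10.0
2,2,6.4;11.4,17.8,4.5,5.8,11.6
3,2,11.3;7.9,19.2,8.3,7.0,12.5
4,4,16.8;3.7;4.8;15,40.3,9.1,10.8,17.6
5,2,7.8;18,25.8,3.0,8.1,11.0
6,3,9.9;6.7;3,19.6,8.5,7.3,5.7
7,2,2.8;5.4,8.2,12.5,6.4,15.0
8,2,10;5.4,15.4,7.0,8.2,10.7
9,2,7.7;10.3,18,3.2,7.0,4.3
10,3,13.7;10.5;7,31.2,11.9,7.4,5.3
11,2,13.4;8.2,21.6,3.8,3.9,8.8
12,5,4.6;8.8;6.9;2.2;6.4,28.9,10.7,7.8,10.0
13,4,14.4;9.8;13.1;7.3,44.6,12.0,7.8,11.5
14,2,4.3;13.2,17.5,6.0,7.5,6.9
15,2,14.8;8.3,23.1,4.2,3.8,9.9
16,3,10.6;8.7;12,31.3,9.2,5.0,13.6
17,2,7.2;12.4,19.6,11.2,10.0,13.0
18,3,5.9;5.8;5.5,17.2,10.8,7.3,10.0
19,3,6.4;8.6;3.6,18.6,10.4,9.3,10.3
20,4,15.8;8.1;15.2;9.1,48.2,10.6,9.7,8.3
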