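neuron_id,session_id,transients_per_min,auc_per_min,category,is_active,fov_id
1,1,8,8.641190813,high,TRUE,1
2,1,4.8,7.074921333,high,TRUE,1
3,1,1.2,5.811252604,intermediate,TRUE,1
4,1,0.4,5.37447295,intermediate,TRUE,1
5,1,0.2,5.14112363,rare,TRUE,1
6,1,5.2,7.639452511,high,TRUE,1
7,1,0.8,5.356086056,intermediate,TRUE,1
8,1,2.2,6.141352297,intermediate,TRUE,1
9,1,0.2,5.111792628,rare,TRUE,1
10,1,0.2,5.159940432,rare,TRUE,1
11,1,1.4,5.687197912,intermediate,TRUE,1
12,1,0.2,5.222912159,rare,TRUE,1
13,1,5.2,7.617618807,high,TRUE,1
14,1,1,5.728992821,intermediate,TRUE,1
15,1,3.2,7.149664594,intermediate,TRUE,1
16,1,7.8,7.929241164,high,TRUE,1
17,1,7.2,8.129632909,high,TRUE,1
18,1,0.4,5.425682834,intermediate,TRUE,1
19,1,1.4,6.213823916,intermediate,TRUE,1
20,1,0.2,5.0910825,rare,TRUE,1
1,2,8.4,8.515435939,high,TRUE,1
2,2,3.6,7.461659055,intermediate,TRUE,1
3,2,0,4.91152146,rare,FALSE,1
4,2,2.2,6.492668584,intermediate,TRUE,1
5,2,0.8,5.526976701,intermediate,TRUE,1
6,2,5.8,8.282102137,high,TRUE,1
7,2,0,4.743888972,rare,FALSE,1
8,2,0.2,4.91939662,rare,TRUE,1
9,2,0.2,5.35449956,rare,TRUE,1
10,2,0.4,5.152651791,intermediate,TRUE,1
11,2,4.2,7.394551873,high,TRUE,1
12,2,0.2,4.990706141,rare,TRUE,1
13,2,4.6,7.644460612,high,TRUE,1
14,2,1.6,6.099609931,intermediate,TRUE,1
15,2,1.8,6.303133479,intermediate,TRUE,1
16,2,6.6,8.002482398,high,TRUE,1
17,2,5.2,7.7735586,high,TRUE,1
18,2,0.2,4.998300312,rare,TRUE,1
19,2,0.8,5.255040574,intermediate,TRUE,1
20,2,1.4,5.81535301,intermediate,TRUE,1
1,3,8.6,8.308238019,high,TRUE,1
2,3,3.2,7.006370913,intermediate,TRUE,1
3,3,0,4.90469661,rare,FALSE,1
4,3,0.6,5.403816812,intermediate,TRUE,1
5,3,0.6,5.262209841,intermediate,TRUE,1
6,3,5.2,7.846509612,high,TRUE,1
7,3,0.2,5.039932342,rare,TRUE,1
8,3,0.4,5.313438395,intermediate,TRUE,1
9,3,1,5.380229682,intermediate,TRUE,1
10,3,1.2,5.403856233,intermediate,TRUE,1
11,3,6.6,8.04663341,high,TRUE,1
12,3,0.2,5.140045298,rare,TRUE,1
13,3,4.4,7.546924449,high,TRUE,1
14,3,1.6,6.085861902,intermediate,TRUE,1
15,3,1.4,5.890563176,intermediate,TRUE,1
16,3,9.2,8.00537357,high,TRUE,1
17,3,5.2,7.838869362,high,TRUE,1
18,3,1.6,5.829738386,intermediate,TRUE,1
19,3,0.6,5.348833478,intermediate,TRUE,1
20,3,3.2,6.386411748,intermediate,TRUE,1
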