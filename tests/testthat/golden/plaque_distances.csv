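session,neuron_id,distance_um,proximity,border_flag
1,1,44.70358366,distant,FALSE
1,2,48.48094255,distant,FALSE
1,3,82.849907,distant,FALSE
1,4,152.2878145,distant,FALSE
1,5,31.68560949,close,FALSE
1,6,225.2245624,distant,FALSE
1,7,192.3065196,distant,FALSE
1,8,40.85252891,distant,FALSE
1,9,113.3485743,distant,FALSE
1,10,165.7101405,distant,FALSE
1,11,225.6495299,distant,FALSE
1,12,191.8422099,distant,FALSE
1,13,169.8587021,distant,FALSE
1,14,130.8937438,distant,FALSE
1,15,202.7551029,distant,FALSE
1,16,81.45955176,distant,FALSE
1,17,237.6793752,distant,FALSE
1,18,133.761732,distant,FALSE
1,19,95.68384613,distant,FALSE
1,20,234.2588819,distant,FALSE
2,1,42.5669824,distant,FALSE
2,2,45.81041422,distant,FALSE
2,3,80.68601133,distant,FALSE
2,4,151.7622634,distant,FALSE
2,5,29.52157732,close,FALSE
2,6,223.0834105,distant,FALSE
2,7,190.1475941,distant,FALSE
2,8,38.22668417,close,FALSE
2,9,112.903568,distant,FALSE
2,10,163.0451831,distant,FALSE
2,11,222.97426,distant,FALSE
2,12,191.7623793,distant,FALSE
2,13,167.1413437,distant,FALSE
2,14,129.0304966,distant,FALSE
2,15,201.3726663,distant,FALSE
2,16,79.02219494,distant,FALSE
2,17,235.0185333,distant,FALSE
2,18,132.8325512,distant,FALSE
2,19,94.37799541,distant,FALSE
2,20,231.536372,distant,FALSE
3,1,40.1452391,distant,FALSE
3,2,43.14783684,distant,FALSE
3,3,79.07849209,distant,FALSE
3,4,151.7622634,distant,FALSE
3,5,27.4094239,close,FALSE
3,6,221.1681625,distant,FALSE
3,7,188.0036358,distant,FALSE
3,8,35.86901502,close,FALSE
3,9,112.903568,distant,FALSE
3,10,160.4341853,distant,FALSE
3,11,220.3004323,distant,FALSE
3,12,189.0305359,distant,FALSE
3,13,164.4245371,distant,FALSE
3,14,127.2158881,distant,FALSE
3,15,199.294614,distant,FALSE
3,16,77.40286025,distant,FALSE
3,17,232.4130111,distant,FALSE
3,18,130.4227924,distant,FALSE
3,19,92.08871756,distant,FALSE
3,20,228.9162245,distant,FALSE
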