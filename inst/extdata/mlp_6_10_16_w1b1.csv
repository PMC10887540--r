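input,h1,h2,h3,h4,h5,h6,h7,h8,h9,h10
day,5.946,-74.377,-5.191,-0.123,35.947,19.789,69.472,18.844,11.077,-9.741
herb_salvia,-22.188,19.571,2.858,-0.875,-23.021,-1.460,-20.183,-24.839,24.732,-0.049
herb_thyme,23.436,-8.728,-1.138,0.791,23.777,-8.585,5.219,17.235,-22.868,3.855
sample_KC,-0.108,-7.028,3.362,22.847,-16.967,4.949,11.619,30.853,-28.909,-0.042
sample_KG,1.287,-3.620,-2.503,-21.715,8.757,4.618,-37.262,-22.961,22.947,-0.295
sample_KSFE,0.132,21.571,0.872,-1.102,9.015,-19.489,10.619,-15.595,7.802,4.176
bias,1.441,10.877,1.697,-0.082,0.821,-10.059,-15.175,-7.666,1.981,3.787
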