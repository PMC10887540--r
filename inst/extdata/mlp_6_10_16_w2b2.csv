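output,h1,h2,h3,h4,h5,h6,h7,h8,h9,h10,bias
DM,58.183,8.481,32.653,-42.411,-16.508,26.829,35.997,29.942,54.881,-4.307,0.671
Fat,-7.297,-31.416,70.373,-66.801,44.395,-34.262,-97.084,50.442,-64.959,-79.962,-1.562
Ash,-5.044,-7.549,-9.331,14.156,-10.769,-49.339,20.769,-12.630,13.787,-41.212,1.185
ProteinsDM,-35.584,-2.777,39.702,-54.536,3.466,47.129,-5.042,33.668,-52.901,10.158,-2.158
Proteins,-20.417,-3.559,7.086,-9.984,25.723,11.569,-13.381,5.889,-10.779,3.842,-0.324
aw,35.435,16.330,-28.452,38.750,-51.027,-33.065,45.172,-18.905,36.649,-6.693,4.102
pH,-1.433,14.026,11.830,-17.768,25.875,18.149,-44.432,33.513,-16.784,6.469,-0.361
TP,-73.083,-36.334,-15.210,-21.810,19.576,21.696,8.571,-25.220,-22.743,4.998,0.670
DPPH,-18.678,34.277,-50.497,33.291,3.410,-50.724,5.340,17.083,34.110,-28.422,-1.852
ABTS,17.065,0.087,17.405,-23.008,1.717,18.474,3.723,14.220,13.383,3.014,-2.949
FRAP,3.087,6.057,-1.503,2.053,3.001,-1.930,-4.765,5.701,3.037,-0.763,-0.582
Aerobic,65.168,59.848,7.543,-10.703,2.055,3.993,-31.010,23.972,-10.132,-2.797,0.059
Ecoli,16.318,2.112,4.819,-6.670,-10.296,3.710,-7.232,3.367,-6.008,-0.189,0.417
Lmonocytogenes,3.493,-3.286,4.604,-6.459,-3.850,4.743,-11.311,2.547,-10.371,0.625,1.358
Saureus,5.659,-4.874,6.536,-9.038,-5.145,4.751,-15.700,3.467,-14.378,-0.910,0.171
Lactic,7.317,-1.893,1.916,-2.428,-8.363,0.305,-4.583,0.212,-4.536,-1.266,0.608
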