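{"model":"sec_contact_asym_mig","params":{"nu1":0.6,"nu2":2.5,"m12":1.5,"m21":0.5,"T1":0.4,"T2":0.2},"theta":{},"L":60,"n_hap":[8,8],"missingness":0.1,"seed":2024,"site_config":[{"row":3,"col":4},{"row":0,"col":1},{"row":3,"col":0},{"row":0,"col":3},{"row":0,"col":4},{"row":0,"col":1},{"row":0,"col":1},{"row":0,"col":3},{"row":0,"col":4},{"row":3,"col":1},{"row":1,"col":3},{"row":1,"col":1},{"row":3,"col":0},{"row":1,"col":4},{"row":0,"col":2},{"row":0,"col":1},{"row":2,"col":4},{"row":0,"col":6},{"row":0,"col":1},{"row":1,"col":0},{"row":0,"col":1},{"row":0,"col":6},{"row":0,"col":1},{"row":0,"col":1},{"row":0,"col":1},{"row":2,"col":3},{"row":0,"col":1},{"row":1,"col":0},{"row":0,"col":1},{"row":0,"col":1},{"row":3,"col":0},{"row":1,"col":0},{"row":2,"col":5},{"row":0,"col":5},{"row":1,"col":0},{"row":0,"col":1},{"row":0,"col":1},{"row":3,"col":0},{"row":0,"col":3},{"row":0,"col":5},{"row":1,"col":1},{"row":2,"col":0},{"row":0,"col":1},{"row":2,"col":0},{"row":0,"col":1},{"row":1,"col":4},{"row":0,"col":2},{"row":2,"col":0},{"row":0,"col":3},{"row":2,"col":3},{"row":1,"col":0},{"row":0,"col":2},{"row":3,"col":2},{"row":1,"col":0},{"row":0,"col":1},{"row":0,"col":1},{"row":1,"col":0},{"row":6,"col":1},{"row":0,"col":1},{"row":1,"col":0}]}
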