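[{"name":"E_max_lv","lower":1066.576,"upper":15998.64,"init":3733.016},{"name":"E_min_lv","lower":39.9966,"upper":666.61,"init":133.322},{"name":"V0_lv","lower":0,"upper":40,"init":10},{"name":"E_max_rv","lower":266.644,"upper":2666.44,"init":799.932},{"name":"R_sys","lower":600,"upper":6000,"init":1600},{"name":"C_sys","lower":0.0002,"upper":0.006,"init":0.0012},{"name":"C_ao","lower":5e-05,"upper":0.0015,"init":0.00028},{"name":"p0_ven","lower":3999.66,"upper":29330.84,"init":11998.98},{"name":"vent_dur_frac","lower":0.22,"upper":0.45,"init":0.35},{"name":"R_pul","lower":40,"upper":500,"init":140}]
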