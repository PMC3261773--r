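{"Cm":5,"gCa":2,"VCa":50,"vm":-20,"sm":12,"gK":4,"VK":-75,"vn":-5,"sn":10,"taun":43,"gKCa":1.7,"Kd":0.5,"gBK":0.4,"vb":-20,"sb":5.6,"fc":0.01,"alpha":0.0015,"kc":0.16}
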