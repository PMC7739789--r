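activity,soleus_N,gastroc_N
two-legged heel drop,680.6,457.6
one-legged heel drop,1464.0,836.4
one-legged heel drop knee bent,2371.2,475.1
toe walking,1242.6,457.6
hopping,3777.4,1816.8
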