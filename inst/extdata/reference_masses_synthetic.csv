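region,mass_g
red_marrow,1500
bone_surfaces,120
kidneys,299
bladder_wall,50
cortical_surface,4000
trabecular_surface,1000
remainder,62000
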