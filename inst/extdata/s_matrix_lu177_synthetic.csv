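source,target,s_value_Gy_per_MBq_h
cortical_surface,red_marrow,5.7e-7
cortical_surface,bone_surfaces,1.14e-5
cortical_surface,kidneys,1.0e-8
cortical_surface,bladder_wall,2.0e-9
trabecular_surface,red_marrow,1.99e-5
trabecular_surface,bone_surfaces,6.4e-5
trabecular_surface,kidneys,1.0e-8
trabecular_surface,bladder_wall,2.0e-9
red_marrow,red_marrow,3.98e-5
red_marrow,bone_surfaces,8.0e-6
red_marrow,kidneys,1.5e-8
red_marrow,bladder_wall,3.0e-9
kidneys,red_marrow,1.5e-8
kidneys,bone_surfaces,1.0e-8
kidneys,kidneys,2.62e-4
kidneys,bladder_wall,5.0e-9
bladder_content,red_marrow,2.0e-9
bladder_content,bone_surfaces,2.0e-9
bladder_content,kidneys,5.0e-9
bladder_content,bladder_wall,1.5e-5
remainder,red_marrow,1.5e-7
remainder,bone_surfaces,1.5e-7
remainder,kidneys,2.0e-7
remainder,bladder_wall,2.0e-7
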