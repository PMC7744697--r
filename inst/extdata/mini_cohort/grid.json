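{"dims":[16,7,7],"voxel_size":[5,5,5],"affine":[5,0,0,-38,0,5,0,-15,0,0,5,-15],"mask_radius":2,"n_videos":10,"seed":42,"noise_sd":1,"missing_rate":0.05}
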