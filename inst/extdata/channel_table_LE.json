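[{"channel":"trunk_lateral","proximal":"pelvis","distal":"sternum","plane":"xy","sign":1,"unit":"trunk","side":"M"},{"channel":"trunk_ventral","proximal":"pelvis","distal":"sternum","plane":"zy","sign":1,"unit":"trunk","side":"M"},{"channel":"hip_flexion_L","proximal":"pelvis","distal":"thigh_L","plane":"zy","sign":1,"unit":"hip_L","side":"L"},{"channel":"hip_flexion_R","proximal":"pelvis","distal":"thigh_R","plane":"zy","sign":1,"unit":"hip_R","side":"R"},{"channel":"hip_rotation_L","proximal":"pelvis","distal":"thigh_rot_L","plane":"xy","sign":1,"unit":"hip_L","side":"L"},{"channel":"hip_rotation_R","proximal":"pelvis","distal":"thigh_rot_R","plane":"xy","sign":1,"unit":"hip_R","side":"R"},{"channel":"knee_L","proximal":"thigh_L","distal":"shank_L","plane":"zy","sign":1,"unit":"knee_L","side":"L"},{"channel":"knee_R","proximal":"thigh_R","distal":"shank_R","plane":"zy","sign":1,"unit":"knee_R","side":"R"},{"channel":"ankle_L","proximal":"shank_L","distal":"foot_L","plane":"zy","sign":1,"unit":"ankle_L","side":"L"},{"channel":"ankle_R","proximal":"shank_R","distal":"foot_R","plane":"zy","sign":1,"unit":"ankle_R","side":"R"}]
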