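[{"channel":"trunk_lateral","proximal":"pelvis","distal":"sternum","plane":"xy","sign":1,"unit":"trunk","side":"M"},{"channel":"trunk_ventral","proximal":"pelvis","distal":"sternum","plane":"zy","sign":1,"unit":"trunk","side":"M"},{"channel":"shoulder_abd_L","proximal":"sternum","distal":"upper_arm_L","plane":"zy","sign":1,"unit":"shoulder_L","side":"L"},{"channel":"elbow_L","proximal":"upper_arm_L","distal":"forearm_L","plane":"zy","sign":1,"unit":"elbow_L","side":"L"},{"channel":"forearm_prosup_L","proximal":"forearm_L","distal":"prosup_L","plane":"xy","sign":1,"unit":"forearm_L","side":"L"},{"channel":"wrist_L","proximal":"forearm_L","distal":"hand_L","plane":"zy","sign":1,"unit":"wrist_L","side":"L"},{"channel":"fingers_L","proximal":"hand_L","distal":"finger_L","plane":"zy","sign":1,"unit":"fingers_L","side":"L"},{"channel":"shoulder_abd_R","proximal":"sternum","distal":"upper_arm_R","plane":"zy","sign":1,"unit":"shoulder_R","side":"R"},{"channel":"elbow_R","proximal":"upper_arm_R","distal":"forearm_R","plane":"zy","sign":1,"unit":"elbow_R","side":"R"},{"channel":"forearm_prosup_R","proximal":"forearm_R","distal":"prosup_R","plane":"xy","sign":1,"unit":"forearm_R","side":"R"},{"channel":"wrist_R","proximal":"forearm_R","distal":"hand_R","plane":"zy","sign":1,"unit":"wrist_R","side":"R"},{"channel":"fingers_R","proximal":"hand_R","distal":"finger_R","plane":"zy","sign":1,"unit":"fingers_R","side":"R"}]
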