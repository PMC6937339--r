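[{"time_s":0,"percent":50},{"time_s":3,"percent":90},{"time_s":6,"percent":35},{"time_s":9,"percent":75},{"time_s":12,"percent":8},{"time_s":15,"percent":60},{"time_s":18,"percent":92},{"time_s":21,"percent":25},{"time_s":24,"percent":70},{"time_s":27,"percent":10},{"time_s":30,"percent":50}]
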