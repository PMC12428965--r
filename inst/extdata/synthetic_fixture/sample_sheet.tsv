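sample_id	condition	fraction	biological_replicate	technical_replicate
Control_total_b1_t1	Control	total	1	1
Control_total_b1_t2	Control	total	1	2
Control_polysome_b1_t1	Control	polysome	1	1
Control_polysome_b1_t2	Control	polysome	1	2
Control_total_b2_t1	Control	total	2	1
Control_total_b2_t2	Control	total	2	2
Control_polysome_b2_t1	Control	polysome	2	1
Control_polysome_b2_t2	Control	polysome	2	2
Control_total_b3_t1	Control	total	3	1
Control_total_b3_t2	Control	total	3	2
Control_polysome_b3_t1	Control	polysome	3	1
Control_polysome_b3_t2	Control	polysome	3	2
Hardening_total_b1_t1	Hardening	total	1	1
Hardening_total_b1_t2	Hardening	total	1	2
Hardening_polysome_b1_t1	Hardening	polysome	1	1
Hardening_polysome_b1_t2	Hardening	polysome	1	2
Hardening_total_b2_t1	Hardening	total	2	1
Hardening_total_b2_t2	Hardening	total	2	2
Hardening_polysome_b2_t1	Hardening	polysome	2	1
Hardening_polysome_b2_t2	Hardening	polysome	2	2
Hardening_total_b3_t1	Hardening	total	3	1
Hardening_total_b3_t2	Hardening	total	3	2
Hardening_polysome_b3_t1	Hardening	polysome	3	1
Hardening_polysome_b3_t2	Hardening	polysome	3	2
Stress_total_b1_t1	Stress	total	1	1
Stress_total_b1_t2	Stress	total	1	2
Stress_polysome_b1_t1	Stress	polysome	1	1
Stress_polysome_b1_t2	Stress	polysome	1	2
Stress_total_b2_t1	Stress	total	2	1
Stress_total_b2_t2	Stress	total	2	2
Stress_polysome_b2_t1	Stress	polysome	2	1
Stress_polysome_b2_t2	Stress	polysome	2	2
Stress_total_b3_t1	Stress	total	3	1
Stress_total_b3_t2	Stress	total	3	2
Stress_polysome_b3_t1	Stress	polysome	3	1
Stress_polysome_b3_t2	Stress	polysome	3	2
Combo_total_b1_t1	Combo	total	1	1
Combo_total_b1_t2	Combo	total	1	2
Combo_polysome_b1_t1	Combo	polysome	1	1
Combo_polysome_b1_t2	Combo	polysome	1	2
Combo_total_b2_t1	Combo	total	2	1
Combo_total_b2_t2	Combo	total	2	2
Combo_polysome_b2_t1	Combo	polysome	2	1
Combo_polysome_b2_t2	Combo	polysome	2	2
Combo_total_b3_t1	Combo	total	3	1
Combo_total_b3_t2	Combo	total	3	2
Combo_polysome_b3_t1	Combo	polysome	3	1
Combo_polysome_b3_t2	Combo	polysome	3	2
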