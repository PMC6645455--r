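(((t37:0.6950607963,((t10:0.4895517746,(((t20:0.1527000956,((t24:0.06909147346,t16:0.06909147346):0.07455818393,t40:0.1436496574):0.009050438207):0.06321926352,t25:0.2159193591):0.01824053857,(t27:0.1974273512,(((t18:0.0280740851,t34:0.0280740851):0.02287957146,(t21:0.04263602227,t13:0.04263602227):0.00831763429):0.1160299637,t17:0.1669836202):0.03044373098):0.03673254649):0.2553918769):0.03554742955,(((((t22:0.1322678048,(t4:0.1005298199,t23:0.1005298199):0.03173798488):0.002865074294,(t2:0.1268595396,t14:0.1268595396):0.008273339412):0.1133021664,(t36:0.1112407688,t7:0.1112407688):0.1371942767):0.1733800573,(t28:0.24700151,t33:0.24700151):0.1748135928):0.1026164382,(t38:0.2521821604,(t26:0.08210080205,t11:0.08210080205):0.1700813583):0.2722493807):0.0006676631263):0.1699615922):0.1490564937,((t30:0.4471972997,(t32:0.1476901634,t1:0.1476901634):0.2995071364):0.1448610886,(t29:0.3334187274,(((t9:0.1319155222,t3:0.1319155222):0.05444875236,(t31:0.1137487216,(t19:0.04978577926,t35:0.04978577926):0.06396294232):0.07261555294):0.03559803547,t6:0.22196231):0.1114564174):0.2586396609):0.2520589017):0.15588271,((t39:0.4031874058,(t8:0.1713046622,(t5:0.09107496737,t12:0.09107496737):0.08022969486):0.2318827436):0.02532311069,t15:0.4285105165):0.5714894835);
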