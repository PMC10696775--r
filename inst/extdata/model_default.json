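{"strategies":{"IB":{"label":"First-line ibrutinib","first_line_route":"oral","lines":[{"name":"IB_1L","drug":"IB","pfs":"ib1_pfs","os":"ib1_os"},{"name":"ZB_2L","drug":"ZB","pfs":"zb_pfs","os":"zb_os"},{"name":"OB_3L","drug":"OB","pfs":"zb_pfs","os":"zb_os","orr_scaled":true}]},"BE_RI":{"label":"First-line bendamustine plus rituximab","first_line_route":"iv","lines":[{"name":"BERI_1L","drug":"BE_RI_LE","pfs":"beri1_pfs","os":"beri1_os"},{"name":"IB_2L","drug":"IB","pfs":"ib2_pfs","os":"ib2_os"},{"name":"ZB_3L","drug":"ZB","pfs":"zb_pfs","os":"zb_os"}]}},"dists":{"ib1_pfs":{"family":"exponential","params":{"rate":0.00592451}},"ib1_os":{"family":"exponential","params":{"rate":0.00368296}},"beri1_pfs":{"family":"gompertz","params":{"shape":0.02325928,"rate":0.00943535}},"beri1_os":{"family":"exponential","params":{"rate":0.00332761}},"ib2_pfs":{"family":"gamma","params":{"shape":1.1802239,"rate":0.0191373}},"ib2_os":{"family":"exponential","params":{"rate":0.00100394}},"zb_pfs":{"family":"gompertz","params":{"shape":0.0341335,"rate":0.00268049}},"zb_os":{"family":"lognormal","params":{"meanlog":1.59,"sdlog":164.93}}},"probs":{"bsc_after_1L":0.15,"bsc_after_2L3L":0.19,"orr_ob":0.91,"orr_ref":0.91},"costs":{"monthly":{"IB":2360.36,"ZB":2940.04,"OB":2995.66,"BE":1543.1,"RI":1797.48,"LE":5069.89},"per_mg":{"IB":0.2,"ZB":0.33,"OB":0.71,"BE":8.57,"RI":3.59,"LE":12.07},"iv_infusion":0.22,"allocation":0.9,"supportive":2703.17,"hospitalization":1454.95,"sae":{"neutropenia":815.1,"thrombocytopenia":605.63,"febrile_neutropenia":4516.31,"hypertension":968.52},"hypertension_outpatient_annual":129.48,"followup_visit":48.8,"bsc_monthly":299.95,"allo_hsct":59621.17,"eol":12455.19},"utilities":{"efs_oral":0.71,"efs_iv":0.67,"pf_after_1L":0.66,"pf_relapsed":0.42,"death":0,"disutil":{"neutropenia":0.163,"thrombocytopenia":0.108,"febrile_neutropenia":0.15,"hypertension":0.195}},"sae_risks":{"BE_RI":{"neutropenia":0.4034,"thrombocytopenia":0.1477,"febrile_neutropenia":0.0739,"hypertension":0.142},"IB":{"neutropenia":0.15,"thrombocytopenia":0.0667,"febrile_neutropenia":0.0167,"hypertension":0.2944}},"bsa":1.72,"discount_rate":0.05,"wtp":38223.34,"horizon_years":10,"age_entry":70,"life_table":[{"age":65,"qx":0.014},{"age":66,"qx":0.0150646048003808},{"age":67,"qx":0.0162236582158444},{"age":68,"qx":0.0174855394504747},{"age":69,"qx":0.0188593710867631},{"age":70,"qx":0.0203550850359605},{"age":71,"qx":0.0219834943393506},{"age":72,"qx":0.0237563713395219},{"age":73,"qx":0.0256865327867654},{"age":74,"qx":0.0277879324958626},{"age":75,"qx":0.0300757622231119},{"age":76,"qx":0.0325665614928681},{"age":77,"qx":0.0352783371675716},{"age":78,"qx":0.0382306936256788},{"age":79,"qx":0.0414449744885974},{"age":80,"qx":0.044944416921219},{"age":81,"qx":0.0487543196215426},{"age":82,"qx":0.0529022257138452},{"age":83,"qx":0.0574181218675974},{"age":84,"qx":0.062334655081625},{"age":85,"qx":0.0676873687007264},{"age":86,"qx":0.0735149593709911},{"age":87,"qx":0.0798595567914406},{"age":88,"qx":0.0867670282844145},{"age":89,"qx":0.094287310386548},{"age":90,"qx":0.102474769857527},{"age":91,"qx":0.111388596716484},{"age":92,"qx":0.121093232147424},{"age":93,"qx":0.131658834367175},{"age":94,"qx":0.143161785823764},{"age":95,"qx":0.155685245391956},{"age":96,"qx":0.169319749557954},{"age":97,"qx":0.184163866939447},{"age":98,"qx":0.200324910872752},{"age":99,"qx":0.217919715218604},{"age":100,"qx":0.237075478995152}],"allo":{"nrm_monthly_early":0.012,"nrm_monthly_late":0.002,"relapse_monthly_early":0.015,"relapse_monthly_late":0.004,"early_months":24},"toggles":{"background_scope":"pf_only","half_cycle":false,"zb_os_override":null,"psa_cost_dist":"gamma"}}
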