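"hios_id","product_name","payer_type"
65208,"Sierra Gold Choice PPO",COMMERCIAL
88220,"Evergreen Select HMO",COMMERCIAL
80028,"Harbor Advantage Plan",COMMERCIAL
72447,"Summit Complete Care",COMMERCIAL
28818,"Lakeside Medicare Advantage",MEDICARE
18493,"Prairie State Medicaid Managed Care",MEDICAID
13891,"Coastal Bronze EPO",COMMERCIAL
97570,"Canyon Silver HMO",COMMERCIAL
40002,"Northstar Platinum PPO",COMMERCIAL
28791,"Meridian Community Plan",MEDICAID
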