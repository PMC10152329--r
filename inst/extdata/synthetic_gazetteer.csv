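kind,key,city,province
postal_prefix,T6G,Edmonton,Alberta
postal_prefix,T5K,Edmonton,Alberta
postal_prefix,T2P,Calgary,Alberta
postal_prefix,T1Y,Calgary,Alberta
postal_prefix,V6B,Vancouver,British Columbia
postal_prefix,S7K,Saskatoon,Saskatchewan
zip,90210,Beverly Hills,California
zip,10001,New York,New York
name,Edmonton,Edmonton,Alberta
name,Calgary,Calgary,Alberta
name,Vancouver,Vancouver,British Columbia
name,Saskatoon,Saskatoon,Saskatchewan
name,Alberta,,Alberta
name,British Columbia,,British Columbia
name,Saskatchewan,,Saskatchewan
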