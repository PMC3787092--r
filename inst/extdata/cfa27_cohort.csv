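sample_id,tumor_class,stage,cfa27_deletion,ki67,er,her2
T49,Complex carcinoma,T2NXMX,+,35,+,-
T47,Simple tubulopapillary,T1NXMX,+,30,+,-
T30,Osteosarcoma,T3NXM0,+,20,+,+
T52,Simple tubulopapillary,T1NXMX,+,30,+,-
T40,Simple tubulopapillary,T1N0M0,+,35,-,-
T69,Simple solid,T3NXM0,+,45,+,-
T73,Simple solid,T3N0MX,+,45,-,-
T81,Simple solid,T1N0M0,+,35,-,-
T86,Simple solid,T1N0M0,+,45,+,-
T108,Simple carcinoma,T3N0MX,+,ND,ND,-
T35,Simple tubulopapillary,T3NXM0,-,35,+,-
T60,Complex carcinoma,T1N0M0,-,ND,ND,+
T65,Complex carcinoma,T1N0M0,-,15,+,-
T78,Simple tubulopapillary,T1N0M0,-,10,+,-
T92,Carcinosarcoma,T3N0M0,-,10,+,-
T83,Simple tubulopapillary,T3N0M1,-,25,+,+
T98,Simple tubulopapillary,T3N0M0,-,ND,ND,+
T97,Simple tubulopapillary,T3N0M0,-,30,+,-
T99,Complex carcinoma,T3N0M0,-,10,+,-
T104,Simple tubulopapillary,T3N0MX,-,20,+,-
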