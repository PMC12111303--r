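ma_number,name,atc,bdf,ame,isi,rca,trn,ndxup,pack_metadata
037599230,RISPERIDONE SAN 60FILM TAB 2MG,N05AX08,0069,0019,0031,0047,0042,0.4,60 tablets
028752069,RISPERDAL 60TAB 2MG ORANGE,N05AX08,0069,0019,0031,0047,0042,0.4,60 tablets
037092222,RISPERIDONE TE 60FILM TAB 2MG,N05AX08,0069,0019,0031,0047,0042,0.4,60 tablets
040078293,RISPERIDONE AURO 60TAB 2MG,N05AX08,0069,0019,0031,0047,0042,0.4,60 tablets
040616082,RISPERIDONE MY 60FILM TAB 2MG,N05AX08,0069,0019,0031,0047,0042,0.4,60 tablets
028752057,RISPERDAL 60TAB 1MG WHITE,N05AX08,0069,0019,0031,0047,0042,0.2,60 tablets
037092069,RISPERIDONE TE 60FILM TAB 1MG,N05AX08,0069,0019,0031,0047,0042,0.2,60 tablets
037599065,RISPERIDONE SAN 60FILM TAB 1MG,N05AX08,0069,0019,0031,0047,0042,0.2,60 tablets
040078192,RISPERIDONE AURO 60TAB 1MG,N05AX08,0069,0019,0031,0047,0042,0.2,60 tablets
040616043,RISPERIDONE MY 60FILM TAB 1MG,N05AX08,0069,0019,0031,0047,0042,0.2,60 tablets
028752083,RISPERDAL 60TAB 4MG GREEN,N05AX08,0069,0019,0031,0047,0042,0.8,60 tablets
037092549,RISPERIDONE TE 60FILM TAB 4MG,N05AX08,0069,0019,0031,0047,0042,0.8,60 tablets
037599572,RISPERIDONE SAN 60FILM TAB 4MG,N05AX08,0069,0019,0031,0047,0042,0.8,60 tablets
040078495,RISPERIDONE AURO 60TAB 4MG,N05AX08,0069,0019,0031,0047,0042,0.8,60 tablets
040616207,RISPERIDONE MY 60FILM TAB 4MG,N05AX08,0069,0019,0031,0047,0042,0.8,60 tablets
028752071,RISPERDAL 60TAB 3MG YELLOW,N05AX08,0069,0019,0031,0047,0042,0.6,60 tablets
037092386,RISPERIDONE TE 60FILM TAB 3MG,N05AX08,0069,0019,0031,0047,0042,0.6,60 tablets
037599406,RISPERIDONE SAN 60FILM TAB 3MG,N05AX08,0069,0019,0031,0047,0042,0.6,60 tablets
040078394,RISPERIDONE AURO 60TAB 3MG,N05AX08,0069,0019,0031,0047,0042,0.6,60 tablets
040616120,RISPERIDONE MY 60FILM TAB 3MG,N05AX08,0069,0019,0031,0047,0042,0.6,60 tablets
037835030,RISPERIDONE SAND OS DROPS 100ML,N05AX08,0090,0019,0031,0047,0042,0.2,100 mL
038188037,RISPERIDONE MY OS DROPS 100ML,N05AX08,0090,0019,0031,0047,0042,0.2,100 mL
042441028,RISPERIDONE AURO DROPS 100ML,N05AX08,0090,0019,0031,0047,0042,0.2,100 mL
028752095,RISPERDAL OS SOL 100ML 1MG/ML,N05AX08,0083,0019,0031,0047,0042,0.2,100 mL
028752145,RISPERDAL OS SOL 30ML 1MG/ML,N05AX08,0083,0019,0031,0047,0042,0.2,30 mL
049966017,OKEDI IM 1SYR 75MG RP,N05AX08,0085,0011,0033,0045,0042,13.9,1 syringe
049966029,OKEDI IM 1SYR 100MG RP,N05AX08,0085,0011,0033,0045,0042,18.5,1 syringe
028752172,RISPERDAL IM VL 25MG + 1SYR 2ML,N05AX08,0085,0011,0033,0045,0039,4.6,1 vial + 2 mL
028752184,RISPERDAL IM VL 37.5MG + 1SYR 2ML,N05AX08,0085,0011,0033,0045,0039,6.9,1 vial + 2 mL
028752196,RISPERDAL IM VL 50MG + 1SYR 2ML,N05AX08,0085,0011,0033,0045,0039,9.2,1 vial + 2 mL
049100011,RISPERIDONE TE IM 1VL 25MG + 2ML,N05AX08,0085,0011,0033,0045,0039,1.8,1 vial + 2 mL
049100047,RISPERIDONE TE IM VL 37.5MG + 2ML,N05AX08,0085,0011,0033,0045,0039,2.7,1 vial + 2 mL
049100074,RISPERIDONE TE IM 1VL 50MG + 2ML,N05AX08,0085,0011,0033,0045,0039,3.7,1 vial + 2 mL
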