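code,label,detailed
1,Grocery/supermarket,store
27,Store - convenience type,store
28,Store - no additional information,store
7,Cafeteria in a K-12 school,school
2,Restaurant with waiter/waitress,full_service
4,Bar/tavern/lounge,full_service
5,Restaurant - no additional information,full_service
3,Restaurant fast food/pizza,quick_service
6,Cafeteria not in a K-12 school,quick_service
14,Vending machine,quick_service
24,Sport/recreation/entertainment facility,quick_service
25,Street vendor/vending truck,quick_service
9,Family/adult day care center,community_food_program
10,Soup kitchen/shelter/food pantry,community_food_program
11,Meals on Wheels,community_food_program
12,Community food program - other,community_food_program
13,Community program - no additional information,community_food_program
19,Grown by you or someone you know,homegrown
20,Fish caught by you or someone you know,homegrown
8,Child care center,other
15,Common coffee pot or snack tray,other
16,From someone else/gift,other
17,Mail order purchase,other
18,Residential dining facility,other
26,Fundraiser sales,other
91,Other - specify,other
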